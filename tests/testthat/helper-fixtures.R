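# small in-code fixture builders shared across test files

manual_alignment_set <- function(genes, n_codons = NULL) {
  tips <- unique(unlist(lapply(genes, names)))
  sub <- ifelse(grepl("_At$", tips), "At",
                ifelse(grepl("_Dt$", tips), "Dt",
                       ifelse(tips == "Ga", "A",
                              ifelse(tips == "Gr", "D", "out"))))
  structure(list(
    genes = genes,
    tips = data.frame(tip = tips, taxon = sub("_(At|Dt)$", "", tips),
                      subgenome = sub, stringsAsFactors = FALSE),
    n_codons = if (is.null(n_codons)) nchar(genes[[1]][1]) %/% 3 else n_codons
  ), class = "alignment_set")
}

manual_panel <- function(hap, pos, chrom = "chr1") {
  structure(list(chrom = rep(chrom, length(pos)), pos = pos, hap = hap,
                 samples = sprintf("S%02d", seq_len(ncol(hap) / 2))),
            class = "genotype_panel")
}

# history with just three species-split knobs used repeatedly in tests
test_history <- function(...) make_history(split_times = list(...))
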