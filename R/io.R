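# -- fixture I/O ----------------------------------------------------------------
#
# Plain-text interchange: per-gene FASTA alignments (record ids
# taxon|subgenome|gene), Newick with branch lengths in years, VCFv4.2 with
# phased GT, bedGraph-dialect TSV tracks (0-based half-open), TSV tables and
# a JSON truth manifest.

tip_record_id <- function(tips, tip, gene) {
  i <- match(tip, tips$tip)
  paste(tips$taxon[i], tips$subgenome[i], gene, sep = "|")
}

#' Write an alignment set as per-gene FASTA files
#'
#' @param alignments An `alignment_set`.
#' @param dir Output directory (created if needed).
#' @return Character vector of files written, invisibly.
#' @export
write_alignment_fasta <- function(alignments, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  for (g in names(alignments$genes)) {
    aln <- alignments$genes[[g]]
    ids <- vapply(names(aln), tip_record_id, character(1),
                  tips = alignments$tips, gene = g)
    x <- Biostrings::DNAStringSet(unname(aln))
    names(x) <- ids
    f <- file.path(dir, paste0(g, ".fasta"))
    Biostrings::writeXStringSet(x, f)
    files <- c(files, f)
  }
  invisible(files)
}

#' Read per-gene FASTA alignments written by [write_alignment_fasta()]
#'
#' @param dir Directory of `<gene>.fasta` files (ids `taxon|subgenome|gene`).
#' @return An `alignment_set`.
#' @export
read_alignment_set <- function(dir) {
  files <- sort(list.files(dir, pattern = "\\.fasta$", full.names = TRUE))
  if (!length(files)) stop("no .fasta files in ", dir)
  genes <- list()
  tipinfo <- list()
  for (f in files) {
    x <- Biostrings::readDNAStringSet(f)
    parts <- strsplit(names(x), "|", fixed = TRUE)
    g <- parts[[1]][3]
    tip <- vapply(parts, function(p)
      if (p[2] %in% c("At", "Dt")) paste(p[1], p[2], sep = "_") else p[1],
      character(1))
    genes[[g]] <- setNames(as.character(x), tip)
    for (i in seq_along(parts))
      tipinfo[[tip[i]]] <- c(taxon = parts[[i]][1], subgenome = parts[[i]][2])
  }
  tips <- data.frame(tip = names(tipinfo),
                     taxon = vapply(tipinfo, `[[`, "", "taxon"),
                     subgenome = vapply(tipinfo, `[[`, "", "subgenome"),
                     row.names = NULL, stringsAsFactors = FALSE)
  structure(list(genes = genes, tips = tips,
                 n_codons = nchar(genes[[1]][1]) %/% 3),
            class = "alignment_set")
}

#' Write / read an LTR pair set as FASTA (`<id>_5ltr` / `<id>_3ltr`)
#'
#' @param ltr An `ltr_pair_set`.
#' @param path FASTA file.
#' @return `write_ltr_fasta` returns `path` invisibly; `read_ltr_pairs`
#'   returns an `ltr_pair_set`.
#' @export
write_ltr_fasta <- function(ltr, path) {
  x <- Biostrings::DNAStringSet(c(rbind(ltr$five, ltr$three)))
  names(x) <- c(rbind(paste0(ltr$id, "_5ltr"), paste0(ltr$id, "_3ltr")))
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

#' @rdname write_ltr_fasta
#' @export
read_ltr_pairs <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  five <- grepl("_5ltr$", names(x))
  ids5 <- sub("_5ltr$", "", names(x)[five])
  ids3 <- sub("_3ltr$", "", names(x)[!five])
  if (!setequal(ids5, ids3)) stop("unpaired LTR records in ", path)
  o3 <- match(ids5, ids3)
  structure(list(id = ids5, five = unname(as.character(x[five])),
                 three = unname(as.character(x[!five])[o3]), r = NA_real_),
            class = "ltr_pair_set")
}

#' Write / read a presence matrix as TSV
#'
#' @param presence A `presence_matrix`.
#' @param path TSV file (`group` column + one 0/1 column per tip).
#' @return `write_presence_tsv` returns `path` invisibly;
#'   `read_presence_table` returns the data.frame form suitable for
#'   [build_presence_matrix()].
#' @export
write_presence_tsv <- function(presence, path) {
  d <- data.frame(group = presence$groups, presence$matrix,
                  check.names = FALSE)
  data.table::fwrite(d, path, sep = "\t")
  invisible(path)
}

#' @rdname write_presence_tsv
#' @export
read_presence_table <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t"))
}

#' Write a phased genotype panel as VCFv4.2
#'
#' Haplotypes `2k-1` and `2k` form sample k's phased genotype `a|b`; missing
#' alleles are written as `.`.
#'
#' @param panel A `genotype_panel`.
#' @param path Output `.vcf` file.
#' @return `path`, invisibly.
#' @export
write_panel_vcf <- function(panel, path) {
  H <- panel$hap
  al <- matrix(as.character(H), nrow(H), ncol(H))
  al[is.na(H)] <- "."
  gt <- matrix("", nrow(H), ncol(H) / 2)
  for (k in seq_len(ncol(gt)))
    gt[, k] <- paste(al[, 2 * k - 1], al[, 2 * k], sep = "|")
  hdr <- c("##fileformat=VCFv4.2",
           "##source=polyrate",
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", panel$samples), collapse = "\t"))
  body <- paste(panel$chrom, panel$pos,
                sprintf("snp%05d", seq_along(panel$pos)),
                "A", "T", ".", "PASS", ".", "GT",
                apply(gt, 1, paste, collapse = "\t"), sep = "\t")
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a phased genotype panel from VCF
#'
#' Uses VariantAnnotation when available, otherwise a minimal text reader.
#' Genotypes must be phased (`a|b`).
#'
#' @param path A `.vcf` file.
#' @return A `genotype_panel`.
#' @export
read_genotype_panel <- function(path) {
  if (requireNamespace("VariantAnnotation", quietly = TRUE)) {
    v <- VariantAnnotation::readVcf(path)
    gt <- VariantAnnotation::geno(v)$GT
    rr <- as.data.frame(SummarizedExperiment::rowRanges(v))
    chrom <- as.character(rr$seqnames)
    pos <- rr$start
    samples <- colnames(gt)
  } else {
    lines <- readLines(path)
    hdr <- grep("^#CHROM", lines)
    cols <- strsplit(lines[hdr], "\t")[[1]]
    samples <- cols[-(1:9)]
    rec <- strsplit(lines[(hdr + 1):length(lines)], "\t")
    chrom <- vapply(rec, `[[`, "", 1)
    pos <- as.integer(vapply(rec, `[[`, "", 2))
    gt <- t(vapply(rec, function(r) r[-(1:9)], character(length(samples))))
    if (length(samples) == 1) gt <- matrix(gt, ncol = 1)
    colnames(gt) <- samples
  }
  if (any(grepl("/", gt, fixed = TRUE)))
    stop("panel must be phased (found '/' genotype separators)")
  n <- nrow(gt)
  hap <- matrix(NA_integer_, n, 2 * ncol(gt))
  for (k in seq_len(ncol(gt))) {
    parts <- strsplit(gt[, k], "|", fixed = TRUE)
    a1 <- vapply(parts, `[[`, "", 1)
    a2 <- vapply(parts, `[[`, "", 2)
    hap[, 2 * k - 1] <- suppressWarnings(as.integer(a1))
    hap[, 2 * k] <- suppressWarnings(as.integer(a2))
  }
  structure(list(chrom = chrom, pos = pos, hap = hap, samples = colnames(gt)),
            class = "genotype_panel")
}

#' Write / read a bedGraph-dialect track (`chrom start end value`, 0-based)
#'
#' @param track data.frame with `chrom`, `start`, `end`, `value`.
#' @param path TSV file (no header, bedGraph dialect).
#' @return `write_track` returns `path` invisibly; `read_track` the
#'   data.frame.
#' @export
write_track <- function(track, path) {
  data.table::fwrite(track[, c("chrom", "start", "end", "value")], path,
                     sep = "\t", col.names = FALSE)
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  as.data.frame(data.table::fread(path, sep = "\t",
                                  col.names = c("chrom", "start", "end",
                                                "value")))
}

#' Write all simulated fixtures to a directory
#'
#' Accepts any subset of the generator outputs and writes the corresponding
#' files: `alignments/` FASTA, `history.nwk`, `presence.tsv`, `ltr.fasta`,
#' `panel.vcf`, `map_points.tsv`, `meth_<context>.tsv`, `contacts.tsv`,
#' `te.tsv`, and a `truth.json` manifest.  Everything round-trips through
#' the package's readers.
#'
#' @param outputs Named list with any of: `alignments`, `history`,
#'   `presence`, `ltr`, `panel`, `map_points`, `methylation`, `contacts`,
#'   `te`, `truth` (a `sim_truth` or list of them).
#' @param dir Output directory.
#' @return Named character vector of files written, invisibly.
#' @export
write_fixtures <- function(outputs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- c()
  if (!is.null(outputs$alignments)) {
    f <- write_alignment_fasta(outputs$alignments, file.path(dir, "alignments"))
    files <- c(files, setNames(file.path(dir, "alignments"), "alignments"))
  }
  if (!is.null(outputs$history))
    files <- c(files, history = write_history_newick(
      outputs$history, file.path(dir, "history.nwk")))
  if (!is.null(outputs$presence))
    files <- c(files, presence = write_presence_tsv(
      outputs$presence, file.path(dir, "presence.tsv")))
  if (!is.null(outputs$ltr))
    files <- c(files, ltr = write_ltr_fasta(outputs$ltr,
                                            file.path(dir, "ltr.fasta")))
  if (!is.null(outputs$panel))
    files <- c(files, panel = write_panel_vcf(outputs$panel,
                                              file.path(dir, "panel.vcf")))
  if (!is.null(outputs$map_points)) {
    f <- file.path(dir, "map_points.tsv")
    data.table::fwrite(outputs$map_points, f, sep = "\t")
    files <- c(files, map_points = f)
  }
  if (!is.null(outputs$methylation))
    for (ctx in names(outputs$methylation)) {
      f <- file.path(dir, paste0("meth_", ctx, ".tsv"))
      write_track(outputs$methylation[[ctx]], f)
      files <- c(files, setNames(f, paste0("meth_", ctx)))
    }
  if (!is.null(outputs$contacts)) {
    f <- file.path(dir, "contacts.tsv")
    data.table::fwrite(outputs$contacts, f, sep = "\t")
    files <- c(files, contacts = f)
  }
  if (!is.null(outputs$te)) {
    f <- file.path(dir, "te.tsv")
    data.table::fwrite(outputs$te, f, sep = "\t")
    files <- c(files, te = f)
  }
  if (!is.null(outputs$truth)) {
    tr <- outputs$truth
    if (inherits(tr, "sim_truth")) tr <- list(tr)
    ser <- lapply(tr, function(t) unclass(t))
    f <- file.path(dir, "truth.json")
    jsonlite::write_json(ser, f, auto_unbox = TRUE, digits = NA,
                         force = TRUE, null = "null")
    files <- c(files, truth = f)
  }
  invisible(files)
}
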