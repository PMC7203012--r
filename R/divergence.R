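# -- pairwise divergence primitives -------------------------------------------
#
# Two distinct gap policies, both used downstream: p_distance excludes
# columns gapped/ambiguous in either member of the pair (pairwise deletion);
# count_substitution_totals excludes columns gapped/ambiguous in ANY taxon of
# the gene's alignment (set-wide deletion).

# integer codes with NA for '-' and 'N'; any other symbol is an error
seq_codes <- function(s, what = "sequence") {
  x <- strsplit(toupper(s), "")[[1]]
  out <- match(x, NT) - 1L
  bad <- is.na(out) & !(x %in% c("-", "N"))
  if (any(bad))
    stop(what, " contains unsupported symbol(s): ",
         paste(unique(x[bad]), collapse = ", "),
         " (only A, C, G, T, N and '-' are accepted)")
  out
}

#' Gap-excluded p-distance between two aligned sequences
#'
#' Columns containing a gap or N in either sequence are excluded (pairwise
#' deletion); the proportion of mismatches among the remaining columns is
#' returned.  Symmetric in its arguments.
#'
#' @param a,b Aligned sequences of equal length over `A,C,G,T,N,-`.
#' @param gene Optional gene id carried into the record.
#' @param pair Optional length-2 taxon labels.
#' @return One-row data.frame: `gene`, `tip1`, `tip2`, `compared_sites`,
#'   `mismatches`, `p`.
#' @export
p_distance <- function(a, b, gene = NA_character_, pair = c(NA, NA)) {
  if (nchar(a) != nchar(b)) stop("sequences must be the same length")
  xa <- seq_codes(a); xb <- seq_codes(b)
  ok <- !is.na(xa) & !is.na(xb)
  n <- sum(ok)
  if (n == 0) stop("no comparable (gap-free) sites")
  mm <- sum(xa[ok] != xb[ok])
  data.frame(gene = gene, tip1 = pair[1], tip2 = pair[2],
             compared_sites = n, mismatches = mm, p = mm / n,
             stringsAsFactors = FALSE)
}

#' Jukes-Cantor corrected distance
#'
#' `d = -(3/4) log(1 - 4p/3)`; defined for `0 <= p < 0.75`.
#'
#' @param p Observed proportion(s) of differing sites.
#' @return Corrected distance(s), `>= p`.
#' @export
jc_distance <- function(p) {
  if (any(p < 0 | p >= 0.75))
    stop("p-distance saturated or invalid: JC correction requires 0 <= p < 0.75")
  -0.75 * log(1 - 4 * p / 3)
}

# non-throwing variant: NA where saturated
jc_or_na <- function(p) ifelse(p >= 0.75 | p < 0, NA_real_, -0.75 * log(1 - 4 * p / 3))

#' Per-gene p-distance table for tip pairs of an alignment set
#'
#' @param alignments An `alignment_set`.
#' @param pairs Optional list of length-2 character vectors (tip pairs);
#'   default all unordered tip pairs.
#' @return data.table with one row per gene x pair (`gene`, `tip1`, `tip2`,
#'   `compared_sites`, `mismatches`, `p`); genes where a pair has no
#'   comparable sites get `NA` p.
#' @export
pdistance_table <- function(alignments, pairs = NULL) {
  tips <- alignments$tips$tip
  if (is.null(pairs)) {
    cmb <- utils::combn(tips, 2)
    pairs <- lapply(seq_len(ncol(cmb)), function(i) cmb[, i])
  }
  rows <- vector("list", length(alignments$genes) * length(pairs))
  k <- 0
  for (g in names(alignments$genes)) {
    aln <- alignments$genes[[g]]
    codes <- lapply(aln, seq_codes)
    for (pr in pairs) {
      xa <- codes[[pr[1]]]; xb <- codes[[pr[2]]]
      if (is.null(xa) || is.null(xb))
        stop("tip not present in alignment: ", paste(pr, collapse = "/"))
      ok <- !is.na(xa) & !is.na(xb)
      n <- sum(ok)
      mm <- if (n) sum(xa[ok] != xb[ok]) else NA_integer_
      k <- k + 1
      rows[[k]] <- data.frame(gene = g, tip1 = pr[1], tip2 = pr[2],
                              compared_sites = n, mismatches = mm,
                              p = if (n) mm / n else NA_real_,
                              stringsAsFactors = FALSE)
    }
  }
  data.table::rbindlist(rows)
}

#' Total substitution counts for a taxon pair over all genes
#'
#' Sums per-gene mismatch counts between the pair after removing every
#' alignment column in which ANY taxon of that gene's alignment carries a gap
#' or N (set-wide column deletion).  Genes lacking either taxon are skipped
#' and reported.
#'
#' @param alignments An `alignment_set`.
#' @param pair Length-2 character vector of tip labels.
#' @return List of class `substitution_totals`: `pair`, `total_differences`,
#'   `total_sites`, `n_genes_used`, `genes_skipped`.
#' @export
count_substitution_totals <- function(alignments, pair) {
  stopifnot(length(pair) == 2)
  used <- 0L; skipped <- character(0)
  tot_d <- 0L; tot_s <- 0L
  for (g in names(alignments$genes)) {
    aln <- alignments$genes[[g]]
    if (!all(pair %in% names(aln))) { skipped <- c(skipped, g); next }
    codes <- vapply(aln, seq_codes, integer(nchar(aln[[1]])))
    ok <- rowSums(is.na(codes)) == 0
    if (!any(ok)) { skipped <- c(skipped, g); next }
    xa <- codes[ok, pair[1]]; xb <- codes[ok, pair[2]]
    tot_d <- tot_d + sum(xa != xb)
    tot_s <- tot_s + sum(ok)
    used <- used + 1L
  }
  if (used == 0L) stop("no gene contains both taxa with comparable sites")
  structure(list(pair = pair, total_differences = tot_d, total_sites = tot_s,
                 n_genes_used = used, genes_skipped = skipped),
            class = "substitution_totals")
}

#' Nei-Gojobori (1986) Ka/Ks for a codon sequence pair
#'
#' Synonymous site fractions per codon come from the standard genetic code
#' with mutations to stop codons counted as nonsynonymous (so `N + S` equals
#' three times the number of compared codons); multi-position codon
#' differences are averaged over all shortest pathways, excluding pathways
#' that pass through a stop codon.  `pN = Nd/N`, `pS = Sd/S` with sites
#' averaged over the two sequences; Ka and Ks apply the Jukes-Cantor
#' correction.  The ratio is `NA` (flagged) when Ks is 0 or saturated.
#'
#' @param a,b Aligned codon sequences (length a multiple of 3); codons
#'   containing gaps, N, or a stop in either sequence are excluded pairwise.
#' @param gene Optional gene id.
#' @param pair Optional taxon pair labels.
#' @return One-row data.frame: `gene`, `tip1`, `tip2`, `codons_compared`,
#'   `N`, `S`, `Nd`, `Sd`, `pN`, `pS`, `Ka`, `Ks`, `ratio`, `flags`.
#' @export
ng86_ka_ks <- function(a, b, gene = NA_character_, pair = c(NA, NA)) {
  if (nchar(a) != nchar(b)) stop("sequences must be the same length")
  if (nchar(a) %% 3 != 0) stop("sequence length must be a multiple of 3")
  tab <- codon_tables()
  ca <- codons_of(seq_codes(a))
  cb <- codons_of(seq_codes(b))
  ok <- !is.na(ca) & !is.na(cb) & !tab$is_stop[ca] & !tab$is_stop[cb]
  if (!any(ok)) stop("no comparable codons")
  ca <- ca[ok]; cb <- cb[ok]
  nc <- length(ca)
  S <- (sum(tab$syn_sites[ca]) + sum(tab$syn_sites[cb])) / 2
  N <- 3 * nc - S
  Sd <- sum(tab$Sd[cbind(ca, cb)])
  Nd <- sum(tab$Nd[cbind(ca, cb)])
  pS <- if (S > 0) Sd / S else NA_real_
  pN <- if (N > 0) Nd / N else NA_real_
  Ks <- jc_or_na(pS)
  Ka <- jc_or_na(pN)
  flags <- character(0)
  if (!is.na(pS) && pS >= 0.75) flags <- c(flags, "saturated_s")
  if (!is.na(pN) && pN >= 0.75) flags <- c(flags, "saturated_n")
  ratio <- if (!is.na(Ka) && !is.na(Ks) && Ks > 0) Ka / Ks else NA_real_
  if (is.na(ratio)) flags <- c(flags, "undefined_ratio")
  data.frame(gene = gene, tip1 = pair[1], tip2 = pair[2],
             codons_compared = nc, N = N, S = S, Nd = Nd, Sd = Sd,
             pN = pN, pS = pS, Ka = Ka, Ks = Ks, ratio = ratio,
             flags = paste(flags, collapse = ";"), stringsAsFactors = FALSE)
}

#' Per-gene Ka/Ks table for tip pairs of an alignment set
#'
#' @param alignments An `alignment_set`.
#' @param pairs List of length-2 character vectors of tip labels.
#' @return data.table, one row per gene x pair (see [ng86_ka_ks()]).
#' @export
kaks_table <- function(alignments, pairs) {
  if (is.character(pairs) && length(pairs) == 2) pairs <- list(pairs)
  rows <- list()
  for (g in names(alignments$genes)) {
    aln <- alignments$genes[[g]]
    for (pr in pairs)
      rows[[length(rows) + 1]] <-
        ng86_ka_ks(aln[[pr[1]]], aln[[pr[2]]], gene = g, pair = pr)
  }
  data.table::rbindlist(rows)
}
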