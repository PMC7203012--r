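# -- relative-rate inference ---------------------------------------------------
#
# Distribution-level Wilcoxon signed-rank comparisons of per-gene p-distances
# between lineages (relative to an outgroup) and between subgenomes, a
# Tajima-style per-gene rate-shift screen, and a chi-square on summed
# substitution counts.  Wilcoxon convention: zero differences dropped, ties
# midranked, exact null by sign enumeration for small n, normal approximation
# with tie and continuity corrections otherwise.

#' One-sided Wilcoxon signed-rank test
#'
#' Zeros are dropped and ties midranked.  For `n <= exact_max` nonzero
#' differences, the p-value is exact under the null that each signed rank is
#' positive or negative with probability 1/2 (computed by convolution over
#' doubled midranks, equivalent to enumerating all 2^n sign assignments); for
#' larger n a normal approximation with tie and continuity corrections is
#' used.  With `alternative = "auto"` the tested tail follows the sign of the
#' sample median (tie broken by the statistic's side of its null mean).
#'
#' @param delta Numeric vector of paired differences.
#' @param alternative `"auto"`, `"greater"` (positive shift) or `"less"`.
#' @param exact_max Largest n for the exact null (default 25).
#' @return List: `statistic` (W, sum of positive ranks), `n` (nonzero
#'   differences), `p`, `direction` (`"greater"`/`"less"` tail actually
#'   tested), `method`.
#' @export
wilcoxon_signed_rank <- function(delta, alternative = c("auto", "greater", "less"),
                                 exact_max = 25) {
  alternative <- match.arg(alternative)
  delta <- delta[!is.na(delta)]
  delta <- delta[delta != 0]
  n <- length(delta)
  if (n == 0) stop("no signal: all paired differences are zero")
  r <- rank(abs(delta))
  W <- sum(r[delta > 0])
  mu <- n * (n + 1) / 4
  side <- switch(alternative,
                 greater = "greater", less = "less",
                 auto = {
                   med <- median(delta)
                   if (med > 0) "greater" else if (med < 0) "less"
                   else if (W >= mu) "greater" else "less"
                 })
  if (n <= exact_max) {
    # distribution of 2*W over sign assignments by convolution
    vals <- as.integer(round(2 * r))
    tot <- sum(vals)
    cnt <- numeric(tot + 1)          # index = sum + 1
    cnt[1] <- 1
    for (v in vals) {
      shifted <- c(numeric(v), cnt[seq_len(tot + 1 - v)])
      cnt <- cnt + shifted
    }
    w2 <- round(2 * W)
    p <- if (side == "greater")
      sum(cnt[(w2 + 1):(tot + 1)]) / 2^n
    else sum(cnt[1:(w2 + 1)]) / 2^n
    method <- "exact"
  } else {
    tie_sizes <- table(abs(delta))
    sigma2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_sizes^3 - tie_sizes) / 48
    sigma <- sqrt(sigma2)
    p <- if (side == "greater")
      pnorm((W - mu - 0.5) / sigma, lower.tail = FALSE)
    else pnorm((W - mu + 0.5) / sigma)
    method <- "normal"
  }
  list(statistic = W, n = n, p = min(1, p), direction = side, method = method)
}

# fetch p(tipA, tipB) per gene from a pdistance_table (unordered pair)
pdist_lookup <- function(pdist, a, b) {
  pdist <- as.data.frame(pdist)
  sel <- (pdist$tip1 == a & pdist$tip2 == b) |
         (pdist$tip1 == b & pdist$tip2 == a)
  x <- pdist[sel, c("gene", "p")]
  if (!nrow(x)) stop("pair not present in distance table: ", a, " / ", b)
  setNames(x$p, x$gene)
}

rate_test_row <- function(label, tip1, tip2, outgroup, wt, family_size, alpha) {
  p_adj <- min(1, wt$p * family_size)
  faster <- if (p_adj <= alpha) {
    if (wt$direction == "greater") tip1 else tip2
  } else NA_character_
  data.frame(comparison = label, tip1 = tip1, tip2 = tip2,
             outgroup = outgroup, n_genes = wt$n, statistic = wt$statistic,
             p_raw = wt$p, p_adjusted = p_adj, family_size = family_size,
             direction = faster, method = wt$method, stringsAsFactors = FALSE)
}

#' Lineage relative-rate test from per-gene p-distances
#'
#' Per gene, `delta_g = p(tip1, outgroup) - p(tip2, outgroup)`; a one-sided
#' Wilcoxon signed-rank test is run in the direction of the median delta.
#' `direction` names the faster tip when significant at `alpha` after
#' Bonferroni adjustment (`p_adjusted = min(1, p_raw * family_size)`).
#'
#' @param pdist A [pdistance_table()] result.
#' @param tip1,tip2 Tips compared.
#' @param outgroup Reference tip.
#' @param alpha Significance level for calling a direction (default 0.05).
#' @param family_size Bonferroni family size (default 1).
#' @param min_genes Minimum complete genes (default 6).
#' @param alternative Tail to test: `"auto"` (direction of the median delta;
#'   note this data-chosen tail doubles the realized level under the null),
#'   `"greater"` (tip1 faster) or `"less"`.
#' @return One-row data.frame (a RateTestResult).
#' @export
lineage_rate_test <- function(pdist, tip1, tip2, outgroup, alpha = 0.05,
                              family_size = 1, min_genes = 6,
                              alternative = "auto") {
  p1 <- pdist_lookup(pdist, tip1, outgroup)
  p2 <- pdist_lookup(pdist, tip2, outgroup)
  genes <- intersect(names(p1)[!is.na(p1)], names(p2)[!is.na(p2)])
  if (length(genes) < min_genes)
    stop("insufficient genes with both distances defined (", length(genes), ")")
  delta <- p1[genes] - p2[genes]
  if (all(delta == 0)) stop("no signal: all paired differences are zero")
  wt <- wilcoxon_signed_rank(delta, alternative = alternative)
  rate_test_row(paste0(tip1, " vs ", tip2, " | ", outgroup),
                tip1, tip2, outgroup, wt, family_size, alpha)
}

#' Subgenome relative-rate test within a polyploid species
#'
#' Per gene, `delta_g = p(At, A-diploid) - p(Dt, D-diploid)`; otherwise the
#' same machinery as [lineage_rate_test()].  `direction` is the faster
#' subgenome tip when significant.
#'
#' @param pdist A [pdistance_table()] result.
#' @param species Polyploid species label (e.g. `"Gh"`); tips
#'   `<species>_At` / `<species>_Dt` must be present.
#' @param a_outgroup,d_outgroup Diploid reference tips (defaults `Ga`, `Gr`).
#' @inheritParams lineage_rate_test
#' @return One-row data.frame (a RateTestResult).
#' @export
subgenome_rate_test <- function(pdist, species, a_outgroup = "Ga",
                                d_outgroup = "Gr", alpha = 0.05,
                                family_size = 1, min_genes = 6) {
  ta <- paste0(species, "_At"); td <- paste0(species, "_Dt")
  p1 <- pdist_lookup(pdist, ta, a_outgroup)
  p2 <- pdist_lookup(pdist, td, d_outgroup)
  genes <- intersect(names(p1)[!is.na(p1)], names(p2)[!is.na(p2)])
  if (length(genes) < min_genes)
    stop("insufficient genes with both distances defined (", length(genes), ")")
  delta <- p1[genes] - p2[genes]
  if (all(delta == 0)) stop("no signal: all paired differences are zero")
  wt <- wilcoxon_signed_rank(delta)
  rate_test_row(paste0(species, ": At|", a_outgroup, " vs Dt|", d_outgroup),
                ta, td, paste(a_outgroup, d_outgroup, sep = "+"),
                wt, family_size, alpha)
}

#' All tip-pair x outgroup relative-rate tests with one Bonferroni family
#'
#' Runs [lineage_rate_test()] for every unordered pair of `tips` against
#' every element of `outgroups` (skipping combinations where the outgroup is
#' one of the pair); the Bonferroni family is the full set of tests run.
#'
#' @param pdist A [pdistance_table()] result.
#' @param tips Character vector of tips (>= 2).
#' @param outgroups Character vector of outgroups (>= 1).
#' @param alpha Significance level.
#' @return data.frame, one row per test.
#' @export
all_combination_tests <- function(pdist, tips, outgroups, alpha = 0.05) {
  if (length(tips) < 2 || length(outgroups) < 1)
    stop("need >= 2 tips and >= 1 outgroup")
  cmb <- utils::combn(tips, 2)
  combos <- list()
  for (i in seq_len(ncol(cmb)))
    for (og in outgroups)
      if (!og %in% cmb[, i])
        combos[[length(combos) + 1]] <- c(cmb[, i], og)
  fam <- length(combos)
  do.call(rbind, lapply(combos, function(cc)
    lineage_rate_test(pdist, cc[1], cc[2], cc[3],
                      alpha = alpha, family_size = fam)))
}

# unique substitutions in a 3-taxon comparison: sites (gap/N-free in all
# three) where one ingroup tip differs from the reference while the other
# matches it
unique_substitution_counts <- function(s1, s2, ref) {
  x1 <- seq_codes(s1); x2 <- seq_codes(s2); xr <- seq_codes(ref)
  ok <- !is.na(x1) & !is.na(x2) & !is.na(xr)
  m1 <- sum(ok & x1 != xr & x2 == xr)
  m2 <- sum(ok & x2 != xr & x1 == xr)
  c(m1 = m1, m2 = m2)
}

#' Per-gene Tajima-style rate-shift classification
#'
#' For each gene and each subgenome, unique substitution counts are taken at
#' the polyploid tip (`m1`) and its diploid progenitor (`m2`) using the other
#' diploid as reference; `chisq = (m1 - m2)^2 / (m1 + m2)` with 1 df.  Genes
#' significant at `alpha` for the A screen only are `A-shifted`, for the D
#' screen only `D-shifted`, otherwise `indistinguishable` (also when
#' `m1 + m2 = 0`).  The screen is applied per gene without multiplicity
#' correction.
#'
#' @param alignments An `alignment_set` containing `<species>_At`,
#'   `<species>_Dt` and both diploids.
#' @param species Polyploid species label.
#' @param a_outgroup,d_outgroup Diploid tips (defaults `Ga`, `Gr`).
#' @param alpha Per-gene significance level (default 0.05).
#' @return data.table: per gene, counts, chi-squares, p-values and `class`.
#' @export
classify_gene_rate_shifts <- function(alignments, species, a_outgroup = "Ga",
                                      d_outgroup = "Gr", alpha = 0.05) {
  ta <- paste0(species, "_At"); td <- paste0(species, "_Dt")
  tajima_p <- function(m) {
    tot <- unname(m[1] + m[2])
    if (tot == 0) return(c(chisq = 0, p = 1))
    x2 <- unname((m[1] - m[2])^2 / tot)
    c(chisq = x2, p = pchisq(x2, df = 1, lower.tail = FALSE))
  }
  rows <- lapply(names(alignments$genes), function(g) {
    aln <- alignments$genes[[g]]
    need <- c(ta, td, a_outgroup, d_outgroup)
    if (!all(need %in% names(aln)))
      stop("gene ", g, " lacks required taxa: ",
           paste(setdiff(need, names(aln)), collapse = ", "))
    mA <- unique_substitution_counts(aln[[ta]], aln[[a_outgroup]], aln[[d_outgroup]])
    mD <- unique_substitution_counts(aln[[td]], aln[[d_outgroup]], aln[[a_outgroup]])
    sA <- tajima_p(mA); sD <- tajima_p(mD)
    sigA <- sA["p"] <= alpha; sigD <- sD["p"] <= alpha
    cls <- if (sigA && !sigD) "A-shifted"
           else if (sigD && !sigA) "D-shifted"
           else "indistinguishable"
    data.frame(gene = g, m1_A = mA[1], m2_A = mA[2],
               chisq_A = sA["chisq"], p_A = sA["p"],
               m1_D = mD[1], m2_D = mD[2],
               chisq_D = sD["chisq"], p_D = sD["p"],
               class = cls, stringsAsFactors = FALSE, row.names = NULL)
  })
  data.table::rbindlist(rows)
}

#' Chi-square goodness-of-fit on total substitution counts
#'
#' Tests observed per-pair total substitution counts against an equal-counts
#' expectation (default) or a supplied expectation; `df = cells - 1`.
#'
#' @param totals List of [count_substitution_totals()] results, or a numeric
#'   vector of counts.
#' @param expected Optional expected counts or proportions (recycled/scaled
#'   to the observed total).
#' @return List of class `chi_square_result`: `observed`, `expected`,
#'   `statistic`, `df`, `p`.
#' @export
chisq_substitution_totals <- function(totals, expected = NULL) {
  obs <- if (is.numeric(totals)) totals else
    vapply(totals, function(t) as.numeric(t$total_differences), numeric(1))
  if (length(obs) < 2) stop("need at least 2 cells")
  if (any(obs < 0)) stop("counts must be >= 0")
  exp_counts <- if (is.null(expected)) rep(sum(obs) / length(obs), length(obs))
  else {
    if (length(expected) != length(obs))
      stop("expected must match the number of observed cells")
    expected / sum(expected) * sum(obs)
  }
  if (any(exp_counts == 0)) stop("expected cell count of zero")
  stat <- sum((obs - exp_counts)^2 / exp_counts)
  df <- length(obs) - 1
  structure(list(observed = obs, expected = exp_counts, statistic = stat,
                 df = df, p = pchisq(stat, df, lower.tail = FALSE)),
            class = "chi_square_result")
}
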