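# -- recombination landscape and epigenome correlation --------------------------
#
# Haplotype-block (recombination cold spot) detection from a phased panel via
# D' with bootstrap confidence bounds (Gabriel-inspired: a "strong LD" pair
# has upper CI bound >= 0.90 AND lower bound >= 0.70), Marey-map local
# regression of genetic on physical position, window-level aggregation of
# methylation and chromatin-contact summaries, and hot/cold correlation.
# Coordinates are 0-based half-open internally; VCF positions are 1-based on
# ingest.

#' Filter a genotype panel on MAF and missingness
#'
#' Retains SNPs with minor allele frequency strictly greater than `maf_min`
#' and missing rate strictly less than `missing_max`.
#'
#' @param panel A `genotype_panel`.
#' @param maf_min MAF threshold (default 0.05, strict >).
#' @param missing_max Missing-rate threshold (default 0.10, strict <).
#' @return The filtered `genotype_panel`, with attribute `filter_counts`
#'   (`n_in`, `n_kept`).
#' @export
filter_panel <- function(panel, maf_min = 0.05, missing_max = 0.10) {
  st <- panel_stats(panel)
  keep <- st$maf > maf_min & st$missing < missing_max
  if (!any(keep)) stop("no SNPs pass the filters")
  out <- structure(list(chrom = panel$chrom[keep], pos = panel$pos[keep],
                        hap = panel$hap[keep, , drop = FALSE],
                        samples = panel$samples),
                   class = "genotype_panel")
  attr(out, "filter_counts") <- c(n_in = length(keep), n_kept = sum(keep))
  out
}

# D' from the 2x2 haplotype frequency table (p11 = freq of 1/1)
dprime_from_freqs <- function(p1, p2, p11) {
  D <- p11 - p1 * p2
  dmax <- if (D >= 0) min(p1 * (1 - p2), (1 - p1) * p2)
  else min(p1 * p2, (1 - p1) * (1 - p2))
  if (dmax == 0) return(NA_real_)
  D / dmax
}

#' D' between two loci with a bootstrap confidence bound
#'
#' `D = p11 - p1 p2`, `D' = D / Dmax` with the standard bound.  The
#' confidence interval (default 90%) of |D'| is obtained by a seeded
#' parametric bootstrap of the four haplotype counts.
#'
#' @param a,b Phased haplotype vectors (0/1, NA allowed; pairs with missing
#'   data are dropped), or `a` may be a length-4 count vector
#'   `c(n00, n01, n10, n11)` with `b` omitted.
#' @param n_boot Bootstrap resamples (default 200).
#' @param conf Confidence level for the |D'| interval (default 0.90).
#' @param seed Seed for the bootstrap (default 1).
#' @return List: `dprime` (signed), `abs_dprime`, `ci_lower`, `ci_upper`
#'   (bounds on |D'|), `n` (haplotypes used).
#' @export
dprime <- function(a, b = NULL, n_boot = 200, conf = 0.90, seed = 1) {
  if (is.null(b)) {
    if (length(a) != 4) stop("counts form requires c(n00, n01, n10, n11)")
    cnt <- as.numeric(a)
  } else {
    ok <- !is.na(a) & !is.na(b)
    a <- a[ok]; b <- b[ok]
    cnt <- c(sum(a == 0 & b == 0), sum(a == 0 & b == 1),
             sum(a == 1 & b == 0), sum(a == 1 & b == 1))
  }
  n <- sum(cnt)
  if (n < 4) stop("need at least 4 haplotypes")
  p1 <- (cnt[3] + cnt[4]) / n
  p2 <- (cnt[2] + cnt[4]) / n
  if (p1 %in% c(0, 1) || p2 %in% c(0, 1))
    stop("monomorphic locus: D' undefined")
  dp <- dprime_from_freqs(p1, p2, cnt[4] / n)
  set.seed(seed)
  bs <- rmultinom(n_boot, n, cnt / n)
  q1 <- (bs[3, ] + bs[4, ]) / n
  q2 <- (bs[2, ] + bs[4, ]) / n
  p11 <- bs[4, ] / n
  D <- p11 - q1 * q2
  dmax <- ifelse(D >= 0, pmin(q1 * (1 - q2), (1 - q1) * q2),
                 pmin(q1 * q2, (1 - q1) * (1 - q2)))
  bdp <- abs(D / dmax)
  bdp <- bdp[q1 > 0 & q1 < 1 & q2 > 0 & q2 < 1 & dmax > 0]
  alpha <- (1 - conf) / 2
  ci <- if (length(bdp)) quantile(bdp, c(alpha, 1 - alpha), names = FALSE)
  else c(NA_real_, NA_real_)
  list(dprime = dp, abs_dprime = abs(dp),
       ci_lower = ci[1], ci_upper = ci[2], n = n)
}

# 2D prefix sums over an upper-triangular pair matrix; query = sum over
# a <= i < j <= b
pair_prefix <- function(M) apply(t(apply(M, 1, cumsum)), 2, cumsum)

pair_range_sum <- function(C, a, b) {
  f <- function(i, j) if (i < 1 || j < 1) 0 else C[i, j]
  f(b, b) - f(a - 1, b) - f(b, a - 1) + f(a - 1, a - 1)
}

#' Call haplotype blocks (recombination cold spots) from a phased panel
#'
#' Gabriel-style partition: SNP pairs (within `max_span_snps`) are classified
#' by the bootstrap CI of |D'| as strong LD (`ci_upper >= dprime_upper_min`
#' and `ci_lower >= dprime_lower_min`), strong recombination evidence
#' (`ci_upper < dprime_upper_min`), or uninformative.  A candidate run of
#' SNPs is a block when its outermost pair is strong and the fraction of its
#' informative pairs in strong LD exceeds `strong_frac_min`; candidates are
#' accepted greedily longest-first, non-overlapping.
#'
#' @param panel A filtered, phased `genotype_panel`.
#' @param dprime_upper_min Upper CI bound threshold (default 0.90).
#' @param dprime_lower_min Lower CI bound threshold (default 0.70).
#' @param strong_frac_min Required strong-LD fraction among informative pairs
#'   (default 0.95).
#' @param max_span_snps Maximum SNPs per block (default 50).
#' @param n_boot Bootstrap resamples per pair (default 100).
#' @param conf CI level (default 0.90).
#' @param seed Seed for the pair bootstraps.
#' @return data.frame of class `haplotype_blocks`: `chrom`, `start`, `end`
#'   (0-based half-open), `n_snps`, `mean_abs_dprime`; sorted,
#'   non-overlapping, each with >= 2 SNPs.
#' @export
call_blocks <- function(panel, dprime_upper_min = 0.90,
                        dprime_lower_min = 0.70, strong_frac_min = 0.95,
                        max_span_snps = 50, n_boot = 100, conf = 0.90,
                        seed = 1) {
  out <- list()
  for (ch in unique(panel$chrom)) {
    idx <- which(panel$chrom == ch)
    if (length(idx) < 2) next
    pos <- panel$pos[idx]
    if (is.unsorted(pos, strictly = TRUE))
      stop("SNP positions must be strictly increasing per chromosome")
    H <- panel$hap[idx, , drop = FALSE]
    n <- length(idx)
    strong <- matrix(0, n, n)
    inform <- matrix(0, n, n)
    absdp <- matrix(NA_real_, n, n)
    for (i in seq_len(n - 1)) {
      for (j in (i + 1):min(n, i + max_span_snps - 1)) {
        d <- tryCatch(dprime(H[i, ], H[j, ], n_boot = n_boot, conf = conf,
                             seed = seed + 131 * i + j),
                      error = function(e) NULL)
        if (is.null(d) || is.na(d$ci_upper)) next
        absdp[i, j] <- d$abs_dprime
        if (d$ci_upper >= dprime_upper_min) {
          if (d$ci_lower >= dprime_lower_min) {
            strong[i, j] <- 1; inform[i, j] <- 1
          }                                   # else uninformative (wide CI)
        } else inform[i, j] <- 1              # recombination evidence
      }
    }
    Cs <- pair_prefix(strong)
    Ci <- pair_prefix(inform)
    cand <- expand.grid(a = seq_len(n), len = 2:min(max_span_snps, n))
    cand$b <- cand$a + cand$len - 1
    cand <- cand[cand$b <= n, ]
    cand <- cand[order(-cand$len, cand$a), ]
    taken <- rep(FALSE, n)
    for (r in seq_len(nrow(cand))) {
      a <- cand$a[r]; b <- cand$b[r]
      if (any(taken[a:b])) next
      if (strong[a, b] != 1) next             # outermost pair must be strong
      ni <- pair_range_sum(Ci, a, b)
      if (ni < 1) next
      ns <- pair_range_sum(Cs, a, b)
      if (ns / ni <= strong_frac_min && ns != ni) next
      taken[a:b] <- TRUE
      dps <- absdp[a:b, a:b]
      out[[length(out) + 1]] <- data.frame(
        chrom = ch, start = pos[a] - 1, end = pos[b], n_snps = b - a + 1,
        mean_abs_dprime = mean(dps[upper.tri(dps)], na.rm = TRUE),
        stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    blocks <- data.frame(chrom = character(0), start = numeric(0),
                         end = numeric(0), n_snps = integer(0),
                         mean_abs_dprime = numeric(0))
  else {
    blocks <- do.call(rbind, out)
    blocks <- blocks[order(blocks$chrom, blocks$start), ]
    rownames(blocks) <- NULL
  }
  stopifnot(all(blocks$n_snps >= 2))
  if (nrow(blocks) > 1)
    for (ch in unique(blocks$chrom)) {
      bb <- blocks[blocks$chrom == ch, ]
      stopifnot(!is.unsorted(bb$start), all(bb$start[-1] >= bb$end[-nrow(bb)]))
    }
  class(blocks) <- c("haplotype_blocks", "data.frame")
  blocks
}

#' Marey-map recombination rates by local linear regression
#'
#' Fits a tricube-weighted local linear regression of genetic position (cM)
#' on physical position, using the `span_fraction` nearest markers (default
#' 7.5% of the chromosome's markers); the local slope at each window midpoint
#' is the recombination rate in cM/Mb.  Windows with fewer than `min_snps`
#' markers are no-calls; negative local slopes are reported raw with a flag
#' and clamped to 0 in `rate`.
#'
#' @param map_points data.frame with `chrom`, `pos` (bp), `cM`.
#' @param span_fraction Fraction of markers in each local fit (default 0.075).
#' @param window Window size in bp (default 1e6, non-overlapping).
#' @param min_snps Minimum markers per window (default 4).
#' @return data.frame of class `marey_track`: `chrom`, `start`, `end`,
#'   `n_snps`, `rate_raw`, `rate`, `flag`.
#' @export
marey_rates <- function(map_points, span_fraction = 0.075, window = 1e6,
                        min_snps = 4) {
  rows <- list()
  for (ch in unique(map_points$chrom)) {
    mp <- map_points[map_points$chrom == ch, ]
    mp <- mp[order(mp$pos), ]
    n <- nrow(mp)
    if (n < 10) stop("need >= 10 markers per chromosome")
    if (length(unique(mp$pos)) == 1)
      stop("all markers colinear at one position")
    viol <- sum(diff(mp$cM) < 0)
    if (viol > 0)
      warning(sprintf("%d non-monotone genetic positions on %s", viol, ch))
    q <- max(2, ceiling(span_fraction * n))
    ws <- seq(0, max(mp$pos) - 1, by = window)
    for (w in ws) {
      mid <- w + window / 2
      n_in <- sum(mp$pos - 1 >= w & mp$pos - 1 < w + window)
      if (n_in < min_snps) {
        rows[[length(rows) + 1]] <- data.frame(
          chrom = ch, start = w, end = w + window, n_snps = n_in,
          rate_raw = NA_real_, rate = NA_real_, flag = "no_call")
        next
      }
      d <- abs(mp$pos - mid)
      nn <- order(d)[seq_len(q)]
      dmax <- max(d[nn])
      wts <- if (dmax > 0) (1 - pmin(d[nn] / dmax, 1)^3)^3 else rep(1, q)
      wts[wts <= 0] <- 1e-9
      x <- mp$pos[nn]; y <- mp$cM[nn]
      xb <- sum(wts * x) / sum(wts); yb <- sum(wts * y) / sum(wts)
      sxx <- sum(wts * (x - xb)^2)
      slope <- if (sxx > 0) sum(wts * (x - xb) * (y - yb)) / sxx else NA_real_
      rate_raw <- slope * 1e6
      flag <- if (is.na(rate_raw)) "colinear"
      else if (rate_raw < 0) "negative" else ""
      rows[[length(rows) + 1]] <- data.frame(
        chrom = ch, start = w, end = w + window, n_snps = n_in,
        rate_raw = rate_raw, rate = if (is.na(rate_raw)) NA_real_
        else max(0, rate_raw), flag = flag)
    }
  }
  track <- do.call(rbind, rows)
  rownames(track) <- NULL
  class(track) <- c("marey_track", "data.frame")
  track
}

overlap_bp <- function(s1, e1, s2, e2) pmax(0, pmin(e1, e2) - pmax(s1, s2))

#' Aggregate blocks, methylation and contacts into analysis windows
#'
#' Windows of `window` bp tile the chromosome; a window is cold when blocks
#' cover more than half its length.  Methylation sub-windows (1-kb bedGraph
#' dialect) are aggregated by coverage-weighted mean per context; contact
#' records are assigned to windows by their anchor interval, counting those
#' with intensity above `strong_threshold`.
#'
#' @param blocks `haplotype_blocks` (or any data.frame with `chrom`,
#'   `start`, `end`).
#' @param methylation Named list (context -> data.frame `chrom`, `start`,
#'   `end`, `value` with values in [0,1]).
#' @param contacts data.frame `chrom`, `start`, `end`, `intensity`,
#'   `distance` (one row per contact).
#' @param strong_threshold Intensity cutoff for a strong contact (default 5).
#' @param window Analysis window size in bp (default 1e6).
#' @param chrom_length Chromosome length; inferred from the tracks if NULL.
#' @return data.frame of class `landscape_windows`: per window `chrom`,
#'   `start`, `end`, `is_cold`, one `meth_<context>` column per context,
#'   `n_contacts`, `n_strong_contacts`, `mean_intensity`,
#'   `mean_contact_distance`.
#' @export
summarize_windows <- function(blocks, methylation, contacts,
                              strong_threshold = 5, window = 1e6,
                              chrom_length = NULL) {
  chroms <- unique(c(blocks$chrom, unlist(lapply(methylation, `[[`, "chrom")),
                     contacts$chrom))
  chroms <- chroms[!is.na(chroms)]
  if (length(chroms) != 1)
    stop("summarize_windows expects a single chromosome; got: ",
         paste(chroms, collapse = ", "))
  if (is.null(chrom_length))
    chrom_length <- max(vapply(methylation, function(t) max(t$end), numeric(1)),
                        if (nrow(contacts)) max(contacts$end) else 0)
  ws <- seq(0, chrom_length - 1, by = window)
  we <- pmin(ws + window, chrom_length)
  nw <- length(ws)
  cold <- vapply(seq_len(nw), function(i) {
    if (!nrow(blocks)) return(FALSE)
    sum(overlap_bp(ws[i], we[i], blocks$start, blocks$end)) >
      0.5 * (we[i] - ws[i])
  }, logical(1))
  res <- data.frame(chrom = chroms, start = ws, end = we, is_cold = cold)
  for (ctx in names(methylation)) {
    tr <- methylation[[ctx]]
    if (any(tr$value < 0 | tr$value > 1))
      stop("methylation values must lie in [0, 1] (context ", ctx, ")")
    v <- vapply(seq_len(nw), function(i) {
      ov <- overlap_bp(ws[i], we[i], tr$start, tr$end)
      if (sum(ov) == 0) return(NA_real_)
      sum(ov * tr$value) / sum(ov)
    }, numeric(1))
    res[[paste0("meth_", ctx)]] <- v
  }
  wi <- if (nrow(contacts))
    findInterval((contacts$start + contacts$end) / 2, c(ws, chrom_length))
  else integer(0)
  res$n_contacts <- as.integer(tabulate(wi, nbins = nw))
  res$n_strong_contacts <- as.integer(tabulate(
    wi[contacts$intensity > strong_threshold], nbins = nw))
  res$mean_intensity <- vapply(seq_len(nw), function(i)
    if (any(wi == i)) mean(contacts$intensity[wi == i]) else NA_real_,
    numeric(1))
  res$mean_contact_distance <- vapply(seq_len(nw), function(i)
    if (any(wi == i)) mean(contacts$distance[wi == i]) else NA_real_,
    numeric(1))
  class(res) <- c("landscape_windows", "data.frame")
  res
}

#' Correlate the recombination landscape with methylation and contacts
#'
#' For each window variable (methylation per context and the contact
#' summaries), reports the point-biserial Pearson correlation with cold-spot
#' membership and a one-way ANOVA (cold vs hot) F and p.
#'
#' @param windows A `landscape_windows` data.frame (>= 10 windows, both
#'   classes present).
#' @return data.frame: `variable`, `n`, `mean_cold`, `mean_hot`, `r`, `F`,
#'   `p`; `r` is NA when a variable has zero variance.
#' @export
correlate_landscape <- function(windows) {
  if (nrow(windows) < 10) stop("need >= 10 windows")
  if (length(unique(windows$is_cold)) < 2)
    stop("both cold and hot windows are required")
  vars <- c(grep("^meth_", names(windows), value = TRUE),
            "n_strong_contacts", "mean_intensity", "mean_contact_distance")
  vars <- intersect(vars, names(windows))
  g <- as.numeric(windows$is_cold)
  rows <- lapply(vars, function(v) {
    x <- windows[[v]]
    ok <- !is.na(x)
    xi <- x[ok]; gi <- g[ok]
    n <- length(xi)
    if (n < 3 || length(unique(gi)) < 2)
      return(data.frame(variable = v, n = n, mean_cold = NA, mean_hot = NA,
                        r = NA_real_, F = NA_real_, p = NA_real_))
    r <- if (sd(xi) == 0) NA_real_ else cor(xi, gi)
    m1 <- mean(xi[gi == 1]); m0 <- mean(xi[gi == 0])
    n1 <- sum(gi == 1); n0 <- sum(gi == 0)
    ssb <- n1 * (m1 - mean(xi))^2 + n0 * (m0 - mean(xi))^2
    ssw <- sum((xi[gi == 1] - m1)^2) + sum((xi[gi == 0] - m0)^2)
    Fst <- if (ssw == 0) NA_real_ else (ssb / 1) / (ssw / (n - 2))
    p <- if (is.na(Fst)) NA_real_ else
      stats::pf(Fst, 1, n - 2, lower.tail = FALSE)
    data.frame(variable = v, n = n, mean_cold = m1, mean_hot = m0,
               r = r, F = Fst, p = p, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
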