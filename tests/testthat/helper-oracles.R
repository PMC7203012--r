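# Independent oracles, deliberately implemented with different machinery than
# the package (string/character operations, recursion, enumeration) so that
# agreement is informative.

GC_TAB <- Biostrings::GENETIC_CODE

`%||%` <- function(a, b) if (is.null(a)) b else a

# -- naive per-column p-distance ------------------------------------------------
oracle_pdist <- function(a, b) {
  ca <- strsplit(toupper(a), "")[[1]]
  cb <- strsplit(toupper(b), "")[[1]]
  n <- 0L; mm <- 0L
  for (i in seq_along(ca)) {
    if (ca[i] %in% c("-", "N") || cb[i] %in% c("-", "N")) next
    n <- n + 1L
    if (ca[i] != cb[i]) mm <- mm + 1L
  }
  list(sites = n, mismatches = mm, p = if (n) mm / n else NA_real_)
}

# -- NG86 with on-the-fly recursion ---------------------------------------------
oracle_syn_sites <- function(codon) {
  s <- 0
  aa <- GC_TAB[[codon]]
  for (p in 1:3) for (alt in setdiff(c("A", "C", "G", "T"),
                                     substr(codon, p, p))) {
    mut <- codon
    substr(mut, p, p) <- alt
    if (!is.na(GC_TAB[mut]) && GC_TAB[[mut]] != "*" && GC_TAB[[mut]] == aa)
      s <- s + 1
  }
  s / 3
}

# enumerate all orderings of differing positions; each path is a sequence of
# single-nucleotide steps; returns matrix of (syn, nonsyn) per stop-free path
oracle_paths <- function(c1, c2, allow_stops = FALSE) {
  d <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  if (!length(d)) return(matrix(0, 1, 2))
  res <- list()
  recurse <- function(cur, remaining, s, n) {
    if (!length(remaining)) { res[[length(res) + 1]] <<- c(s, n); return() }
    for (p in remaining) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      if (GC_TAB[[nxt]] == "*" && !allow_stops) next
      syn <- GC_TAB[[nxt]] != "*" && GC_TAB[[cur]] != "*" &&
        GC_TAB[[nxt]] == GC_TAB[[cur]]
      recurse(nxt, setdiff(remaining, p), s + syn, n + !syn)
    }
  }
  recurse(c1, d, 0, 0)
  if (!length(res)) return(NULL)
  do.call(rbind, res)
}

oracle_ng86 <- function(a, b) {
  stopifnot(nchar(a) == nchar(b), nchar(a) %% 3 == 0)
  n_cod <- nchar(a) %/% 3
  S <- Sa <- Sb <- 0; Sd <- Nd <- 0; used <- 0
  for (i in seq_len(n_cod)) {
    c1 <- toupper(substr(a, 3 * i - 2, 3 * i))
    c2 <- toupper(substr(b, 3 * i - 2, 3 * i))
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (GC_TAB[[c1]] == "*" || GC_TAB[[c2]] == "*") next
    used <- used + 1
    Sa <- Sa + oracle_syn_sites(c1)
    Sb <- Sb + oracle_syn_sites(c2)
    paths <- oracle_paths(c1, c2)
    if (is.null(paths)) paths <- oracle_paths(c1, c2, allow_stops = TRUE)
    Sd <- Sd + mean(paths[, 1])
    Nd <- Nd + mean(paths[, 2])
  }
  S <- (Sa + Sb) / 2
  N <- 3 * used - S
  pS <- Sd / S; pN <- Nd / N
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  list(codons = used, S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       Ks = jc(pS), Ka = jc(pN))
}

# random stop-free codon sequence (characters)
random_codon_seq <- function(n_codons) {
  sense <- names(GC_TAB)[GC_TAB != "*"]
  paste(sample(sense, n_codons, replace = TRUE), collapse = "")
}

# mutate a codon sequence avoiding stop codons, with roughly n_mut changes
mutate_codons <- function(s, n_mut) {
  x <- strsplit(s, "")[[1]]
  L <- length(x)
  for (k in seq_len(n_mut)) {
    repeat {
      p <- sample.int(L, 1)
      old <- x[p]
      x[p] <- sample(setdiff(c("A", "C", "G", "T"), old), 1)
      cod_i <- (p - 1) %/% 3
      cod <- paste(x[(cod_i * 3 + 1):(cod_i * 3 + 3)], collapse = "")
      if (GC_TAB[[cod]] != "*") break
      x[p] <- old
    }
  }
  paste(x, collapse = "")
}

# -- exact Wilcoxon by full sign enumeration ------------------------------------
oracle_wilcoxon_exact <- function(delta, side) {
  delta <- delta[delta != 0]
  n <- length(delta)
  r <- rank(abs(delta))
  W <- sum(r[delta > 0])
  total <- 0
  hits <- 0
  for (mask in 0:(2^n - 1)) {
    signs <- as.integer(intToBits(mask))[1:n]
    w <- sum(r[signs == 1])
    total <- total + 1
    if (side == "greater" && w >= W) hits <- hits + 1
    if (side == "less" && w <= W) hits <- hits + 1
  }
  hits / total
}

# -- brute-force weighted parsimony (with the package's presence-anchored
#    root prior) over all internal labelings ------------------------------------
oracle_sankoff_cost <- function(tree, pattern, loss_weight, gain_weight) {
  nt <- length(tree$tip.label)
  nn <- tree$Nnode
  best <- Inf
  for (mask in 0:(2^nn - 1)) {
    lab <- c(pattern[tree$tip.label], as.integer(intToBits(mask))[1:nn])
    cost <- if (lab[nt + 1] == 0) gain_weight else 0   # root prior
    for (e in seq_len(nrow(tree$edge))) {
      s <- lab[tree$edge[e, 1]]; t <- lab[tree$edge[e, 2]]
      if (s == 0 && t == 1) cost <- cost + gain_weight
      if (s == 1 && t == 0) cost <- cost + loss_weight
    }
    best <- min(best, cost)
  }
  best
}

# -- D' by the direct formula ----------------------------------------------------
oracle_dprime <- function(n00, n01, n10, n11) {
  n <- n00 + n01 + n10 + n11
  pA <- (n10 + n11) / n
  pB <- (n01 + n11) / n
  D <- n11 / n - pA * pB
  dmax <- if (D >= 0) min(pA * (1 - pB), (1 - pA) * pB)
  else min(pA * pB, (1 - pA) * (1 - pB))
  D / dmax
}

# -- chi-square upper tail by numerical integration of the density ---------------
oracle_chisq_p <- function(x, df) {
  dens <- function(t) t^(df / 2 - 1) * exp(-t / 2) / (2^(df / 2) * gamma(df / 2))
  stats::integrate(dens, x, Inf, rel.tol = 1e-12)$value
}
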