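test_that("p_distance: hand counts, gap exclusion, symmetry, errors", {
  r <- p_distance("AAAA", "AAAT")
  expect_equal(r$p, 0.25)
  expect_equal(r$compared_sites, 4)
  r2 <- p_distance("A-CGT", "AACGT")
  expect_equal(r2$compared_sites, 4)
  expect_equal(r2$p, 0)
  rn <- p_distance("ANCGT", "AACGT")
  expect_equal(rn$compared_sites, 4)
  expect_equal(p_distance("ACGT", "TGCA")$p, 1)
  expect_equal(p_distance("ACGT", "ACGA")$p, p_distance("ACGA", "ACGT")$p)
  expect_error(p_distance("ACG", "ACGT"), "same length")
  expect_error(p_distance("--", "AA"), "comparable")
  expect_error(p_distance("ARGT", "ACGT"), "unsupported symbol")
})

test_that("p_distance agrees with a per-column recount oracle", {
  set.seed(11)
  for (k in 1:25) {
    L <- 1000
    a <- sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                prob = c(rep(0.23, 4), 0.04, 0.04))
    b <- sample(c("A", "C", "G", "T", "N", "-"), L, replace = TRUE,
                prob = c(rep(0.23, 4), 0.04, 0.04))
    a <- paste(a, collapse = ""); b <- paste(b, collapse = "")
    got <- p_distance(a, b)
    want <- oracle_pdist(a, b)
    expect_equal(got$compared_sites, want$sites)
    expect_equal(got$p, want$p)
  }
})

test_that("jc_distance closed form and domain", {
  expect_equal(jc_distance(0), 0)
  expect_equal(jc_distance(0.0739), 0.0777992, tolerance = 1e-6)
  p <- seq(0, 0.7, by = 0.05)
  expect_true(all(diff(jc_distance(p)) > 0))       # monotone
  expect_true(all(jc_distance(p) >= p))            # d >= p
  expect_error(jc_distance(0.75), "saturated")
  expect_error(jc_distance(-0.1), "saturated|invalid")
})

test_that("substitution totals: additivity and set-wide gap rule", {
  g1 <- c(x = "AAAAAAAAAA", y = "AAAAAAATTT", z = "AAAAAAAAAA")  # 3 diffs
  g2 <- c(x = "CCCCCCCCCC", y = "GGGGGCCCCC", z = "CCCCCCCCCC")  # 5 diffs
  aln <- manual_alignment_set(list(gene1 = g1, gene2 = g2), n_codons = 3)
  tot <- count_substitution_totals(aln, c("x", "y"))
  expect_equal(tot$total_differences, 8)
  expect_equal(tot$total_sites, 20)
  # a column gapped in a third taxon is excluded from the pair's count
  g3 <- c(x = "AAAA", y = "TAAA", z = "-AAA")
  aln3 <- manual_alignment_set(list(gene1 = g3), n_codons = 1)
  t3 <- count_substitution_totals(aln3, c("x", "y"))
  expect_equal(t3$total_differences, 0)
  expect_equal(t3$total_sites, 3)
  # genes lacking a taxon are skipped and reported
  aln4 <- manual_alignment_set(list(gene1 = g1, gene2 = c(x = "AC", q = "AC")))
  t4 <- count_substitution_totals(aln4, c("x", "y"))
  expect_equal(t4$n_genes_used, 1)
  expect_equal(t4$genes_skipped, "gene2")
  expect_error(count_substitution_totals(aln4, c("x", "nope")), "no gene")
})

test_that("substitution totals equal a brute-force recount on random sets", {
  set.seed(21)
  genes <- list()
  for (g in 1:6) {
    L <- 60
    base <- sample(c("A", "C", "G", "T"), L, replace = TRUE)
    mk <- function() {
      x <- base
      mut <- runif(L) < 0.1
      x[mut] <- sample(c("A", "C", "G", "T", "-", "N"), sum(mut), replace = TRUE)
      paste(x, collapse = "")
    }
    genes[[paste0("g", g)]] <- c(w = mk(), x = mk(), y = mk(), z = mk())
  }
  aln <- manual_alignment_set(genes, n_codons = 20)
  tot <- count_substitution_totals(aln, c("w", "y"))
  # oracle: column scan over all four taxa
  diffs <- 0; sites <- 0
  for (g in genes) {
    cols <- t(vapply(g, function(s) strsplit(s, "")[[1]],
                     character(nchar(g[1]))))
    ok <- apply(cols, 2, function(cc) all(cc %in% c("A", "C", "G", "T")))
    diffs <- diffs + sum(cols["w", ok] != cols["y", ok])
    sites <- sites + sum(ok)
  }
  expect_equal(tot$total_differences, diffs)
  expect_equal(tot$total_sites, sites)
})

test_that("NG86: trivial and hand-enumerated cases", {
  r0 <- ng86_ka_ks("TTTAAA", "TTTAAA")
  expect_equal(r0$Ka, 0); expect_equal(r0$Ks, 0)
  expect_true(is.na(r0$ratio))
  expect_match(r0$flags, "undefined_ratio")
  expect_equal(r0$N + r0$S, 3 * r0$codons_compared)

  # single codon TTT vs TTA (spec-level hand enumeration)
  r <- ng86_ka_ks("TTT", "TTA")
  expect_equal(r$Nd, 1); expect_equal(r$Sd, 0)
  expect_equal(r$S, 0.5); expect_equal(r$N, 2.5)
  expect_equal(r$pN, 0.4)
  expect_equal(r$Ks, 0)
  expect_true(is.na(r$ratio))

  # codons with gaps/N or stops excluded pairwise
  rg <- ng86_ka_ks("TTTA-AAAA", "TTTAAATAA")   # 2nd codon gapped, 3rd: TAA stop
  expect_equal(rg$codons_compared, 1)
  expect_error(ng86_ka_ks("TTTA", "TTTA"), "multiple of 3")
  expect_error(ng86_ka_ks("---", "AAA"), "no comparable codons")
})

test_that("NG86 matches the exhaustive-pathway oracle on random pairs", {
  set.seed(31)
  for (k in 1:10) {
    a <- random_codon_seq(60)
    b <- mutate_codons(a, 25)
    got <- ng86_ka_ks(a, b)
    want <- oracle_ng86(a, b)
    expect_equal(got$S, want$S, tolerance = 1e-10)
    expect_equal(got$Sd, want$Sd, tolerance = 1e-10)
    expect_equal(got$Nd, want$Nd, tolerance = 1e-10)
    expect_equal(got$Ka, want$Ka, tolerance = 1e-10)
    expect_equal(got$Ks, want$Ks, tolerance = 1e-10)
  }
})

test_that("Ka/Ks consistency: neutral genes near 1, constrained genes below", {
  h <- make_history(split_times = list(gm_split = 15e6,
                                       polyploid_origin = 20e6,
                                       diploids = 25e6))
  s1 <- sim_alignments(h, n_genes = 300, n_codons = 300, omega = 1,
                       seed = 53, taxa = c("Gm_At", "Gh_At"))
  kk1 <- kaks_table(s1$alignments, list(c("Gm_At", "Gh_At")))
  ratio1 <- kk1$ratio[!is.na(kk1$ratio)]
  se1 <- sd(ratio1) / sqrt(length(ratio1))
  expect_lt(abs(mean(ratio1) - 1), 3 * se1)
  s2 <- sim_alignments(h, n_genes = 150, n_codons = 300, omega = 0.2,
                       seed = 54, taxa = c("Gm_At", "Gh_At"))
  kk2 <- kaks_table(s2$alignments, list(c("Gm_At", "Gh_At")))
  expect_lt(mean(kk2$ratio, na.rm = TRUE), 1)
})
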