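test_that("Wilcoxon signed rank: exact small-sample behavior", {
  w <- wilcoxon_signed_rank(c(1, 2, 3))
  expect_equal(w$p, 0.125)                   # 1/2^3
  expect_equal(w$direction, "greater")
  # symmetric deltas: weak evidence, p > 0.5 in the tested tail's complement
  ws <- wilcoxon_signed_rank(c(1, -1, 2, -2, 3, -3))
  expect_gt(ws$p, 0.4)
  # zeros dropped
  wz <- wilcoxon_signed_rank(c(0, 0, 1, 2, 3))
  expect_equal(wz$n, 3)
  expect_equal(wz$p, 0.125)
  expect_error(wilcoxon_signed_rank(c(0, 0)), "no signal")
})

test_that("exact Wilcoxon p equals full sign enumeration for n <= 12", {
  set.seed(7)
  for (n in c(4, 6, 8, 10, 12)) {
    for (rep in 1:3) {
      delta <- round(rnorm(n), 2)
      delta[delta == 0] <- 0.5
      if (rep == 2) delta <- c(delta[1:2], delta[1:2] * -1,
                               delta[-(1:4)])        # force tied |values|
      got <- wilcoxon_signed_rank(delta)
      expect_equal(got$p, oracle_wilcoxon_exact(delta, got$direction),
                   tolerance = 1e-12)
    }
  }
})

test_that("normal approximation is close to the exact tail at n = 25", {
  set.seed(8)
  delta <- rnorm(25) + 0.5
  ex <- wilcoxon_signed_rank(delta, exact_max = 25)
  ap <- wilcoxon_signed_rank(delta, exact_max = 10)
  expect_equal(ap$method, "normal")
  expect_lt(abs(ex$p - ap$p), 0.01)
})

test_that("lineage and subgenome rate tests recover planted asymmetry", {
  # faster A-subgenome lineage for Gh: multiplier on the whole path from the
  # polyploid origin to the Gh_At tip (strong planted asymmetry)
  h <- make_history(multipliers = c(Gh_At = 2.5, polyA = 1.5,
                                    polyA1 = 1.5, polyA2 = 1.5))
  s <- sim_alignments(h, n_genes = 300, n_codons = 200, seed = 71,
                      taxa = c("Gh_At", "Gh_Dt", "Gb_At", "Ga", "Gr"))
  pd <- pdistance_table(s$alignments,
                        list(c("Gh_At", "Ga"), c("Gb_At", "Ga"),
                             c("Gh_Dt", "Gr")))
  lt <- lineage_rate_test(pd, "Gh_At", "Gb_At", "Ga")
  expect_equal(lt$direction, "Gh_At")
  expect_lt(lt$p_adjusted, 0.01)
  st <- subgenome_rate_test(pd, "Gh")
  expect_equal(st$direction, "Gh_At")
  expect_lt(st$p_adjusted, 0.01)
  # identical distance columns -> no signal
  pd0 <- pd[pd$tip1 == "Gh_At" | pd$tip2 == "Gh_At", ]
  expect_error(lineage_rate_test(pd0, "Gh_At", "Gh_At", "Ga"), "no signal")
})

test_that("all_combination_tests builds the right Bonferroni family", {
  h <- make_history()
  s <- sim_alignments(h, n_genes = 30, n_codons = 60, seed = 73)
  tips <- c("Gh_At", "Gb_At", "Gt_At", "Gm_At", "Gd_At")
  outg <- c("Ga", "Gr")
  pairs <- c(lapply(tips, function(t) c(t, "Ga")),
             lapply(tips, function(t) c(t, "Gr")))
  pd <- pdistance_table(s$alignments, pairs)
  res <- all_combination_tests(pd, tips, outg)
  expect_equal(nrow(res), 20)                        # 10 pairs x 2 outgroups
  expect_true(all(res$family_size == 20))
  expect_true(all(res$p_adjusted >= res$p_raw))
  expect_true(all(res$p_adjusted <= 1))
  # 2 tips, 1 outgroup: family of 1, adjusted = raw
  r1 <- all_combination_tests(pd, c("Gh_At", "Gb_At"), "Ga")
  expect_equal(nrow(r1), 1)
  expect_equal(r1$p_adjusted, r1$p_raw)
  expect_error(all_combination_tests(pd, "Gh_At", "Ga"), ">= 2 tips")
})

test_that("per-gene rate-shift classification: arithmetic and classes", {
  # craft a gene: Gh_At has 10 unique substitutions, Ga has 2 (vs Gr reference)
  L <- 60
  ref <- strsplit(paste(rep("ACGT", 15), collapse = ""), "")[[1]]
  tipA <- ref; tipA[1:10] <- ifelse(ref[1:10] == "A", "C", "A")
  ga <- ref; ga[11:12] <- ifelse(ref[11:12] == "A", "G", "A")
  g <- list(gene1 = c(Gh_At = paste(tipA, collapse = ""),
                      Ga = paste(ga, collapse = ""),
                      Gh_Dt = paste(ref, collapse = ""),
                      Gr = paste(ref, collapse = "")))
  cls <- classify_gene_rate_shifts(manual_alignment_set(g, 20), "Gh")
  expect_equal(cls$m1_A, 10)
  expect_equal(cls$m2_A, 2)
  expect_equal(cls$chisq_A, 64 / 12, tolerance = 1e-12)
  expect_equal(cls$p_A, oracle_chisq_p(64 / 12, 1), tolerance = 1e-8)
  expect_equal(cls$class, "A-shifted")
  # m1 = m2 -> chi-square 0, indistinguishable
  g2 <- list(gene1 = c(Gh_At = "AAAA", Ga = "AAAA", Gh_Dt = "AAAA",
                       Gr = "AAAA"))
  cls2 <- classify_gene_rate_shifts(manual_alignment_set(g2, 1), "Gh")
  expect_equal(cls2$chisq_A, 0)
  expect_equal(cls2$class, "indistinguishable")
})

test_that("rate-shift screen is roughly calibrated on neutral simulation", {
  h <- make_history()
  s <- sim_alignments(h, n_genes = 400, n_codons = 150, seed = 79,
                      taxa = c("Gh_At", "Gh_Dt", "Ga", "Gr"))
  cls <- classify_gene_rate_shifts(s$alignments, "Gh", alpha = 0.05)
  shifted <- mean(cls$class != "indistinguishable")
  # two screens at alpha each; discrete counts make the test conservative,
  # so the shifted fraction must stay well under 2 * alpha + slack
  expect_lt(shifted, 0.10)
  expect_true(all(cls$class %in%
                  c("indistinguishable", "A-shifted", "D-shifted")))
})

test_that("chi-square on substitution totals: closed form and oracle", {
  r <- chisq_substitution_totals(c(100, 120))
  expect_equal(r$statistic, (100 - 110)^2 / 110 + (120 - 110)^2 / 110)
  expect_equal(r$df, 1)
  expect_equal(chisq_substitution_totals(c(77, 77, 77))$statistic, 0)
  set.seed(5)
  for (k in 1:5) {
    obs <- rpois(3, 200)
    r3 <- chisq_substitution_totals(obs)
    expect_equal(r3$df, 2)
    expect_equal(r3$p, oracle_chisq_p(r3$statistic, 2), tolerance = 1e-8)
  }
  expect_error(chisq_substitution_totals(5), "at least 2")
  expect_error(chisq_substitution_totals(c(1, 2), expected = c(0, 1)), "zero")
  # accepts substitution_totals objects
  g1 <- c(x = "AAAA", y = "AATT", z = "AAAA")
  aln <- manual_alignment_set(list(g = g1), 1)
  tt <- count_substitution_totals(aln, c("x", "y"))
  r4 <- chisq_substitution_totals(list(tt, tt))
  expect_equal(r4$statistic, 0)
})
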