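test_that("zero split time gives identical sequences; determinism holds", {
  h <- make_history(split_times = list(gb_gd_split = 0))
  s <- sim_alignments(h, n_genes = 3, n_codons = 20, seed = 5,
                      taxa = c("Gb_At", "Gd_At"))
  for (g in s$alignments$genes)
    expect_identical(g[["Gb_At"]], g[["Gd_At"]])

  h2 <- make_history()
  a1 <- sim_alignments(h2, n_genes = 4, n_codons = 15, seed = 9)
  a2 <- sim_alignments(h2, n_genes = 4, n_codons = 15, seed = 9)
  expect_identical(a1$alignments$genes, a2$alignments$genes)
  d1 <- tempfile(); d2 <- tempfile()
  write_alignment_fasta(a1$alignments, d1)
  write_alignment_fasta(a2$alignments, d2)
  for (f in list.files(d1))
    expect_identical(readLines(file.path(d1, f)),
                     readLines(file.path(d2, f)))
  a3 <- sim_alignments(h2, n_genes = 4, n_codons = 15, seed = 10)
  expect_false(identical(a1$alignments$genes, a3$alignments$genes))
  expect_error(sim_alignments(h2, 2, 15), "seed")
  expect_error(sim_alignments(h2, 2, 5, seed = 1), "n_codons")
  expect_error(sim_alignments(h2, 2, 15, omega = 0, seed = 1), "omega")
})

test_that("alignments are stop-free and gap injection works", {
  h <- make_history()
  tab <- codon_tables()
  s <- sim_alignments(h, n_genes = 5, n_codons = 30, omega = 0.5, seed = 3)
  for (g in s$alignments$genes)
    for (seqs in g) {
      cod <- substring(seqs, seq(1, nchar(seqs), 3), seq(3, nchar(seqs), 3))
      expect_false(any(Biostrings::GENETIC_CODE[cod] == "*"))
    }
  sg <- sim_alignments(h, n_genes = 5, n_codons = 50, seed = 3, gap_rate = 0.1)
  gaps <- sum(vapply(sg$alignments$genes, function(g)
    sum(vapply(g, function(x) lengths(regmatches(x, gregexpr("-", x))),
               numeric(1))), numeric(1)))
  expect_gt(gaps, 0)
})

test_that("mean JC distance matches the analytic expectation (calibration)", {
  # pair at 0.63 Ma: proposal intensity d = 2rT per site; accepted fraction
  # under uniform sense codons = 1 - (stop-neighbor fraction), since omega = 1
  h <- make_history()
  n_genes <- 500
  s <- sim_alignments(h, n_genes = n_genes, n_codons = 300, omega = 1,
                      seed = 17, taxa = c("Gm_At", "Gh_At"))
  tab <- codon_tables()
  acc <- mean(rowSums(tab$neighbor_class[tab$sense, ] != "stop") / 9)
  d_expect <- expected_pair_divergence(h, "Gm_At", "Gh_At") * acc
  pd <- pdistance_table(s$alignments, list(c("Gm_At", "Gh_At")))
  dj <- -0.75 * log(1 - 4 * pd$p / 3)
  se <- sd(dj) / sqrt(n_genes)
  expect_lt(abs(mean(dj) - d_expect), 3 * se)
})

test_that("simulated At tips are closer to the A diploid than the D diploid", {
  h <- make_history()
  s <- sim_alignments(h, n_genes = 40, n_codons = 120, seed = 23)
  pd <- pdistance_table(s$alignments,
                        list(c("Gh_At", "Ga"), c("Gh_At", "Gr"),
                             c("Gh_Dt", "Gr"), c("Gh_Dt", "Ga")))
  mean_p <- function(t1, t2)
    mean(pd$p[(pd$tip1 == t1 & pd$tip2 == t2) |
              (pd$tip1 == t2 & pd$tip2 == t1)])
  expect_lt(mean_p("Gh_At", "Ga"), mean_p("Gh_At", "Gr"))
  expect_lt(mean_p("Gh_Dt", "Gr"), mean_p("Gh_Dt", "Ga"))
})

test_that("sim_presence: edge cases, truth consistency, binomial envelope", {
  h <- make_history()
  s0 <- sim_presence(h, 20, loss_rate = 0, gain_rate = 0, seed = 2)
  expect_true(all(s0$presence$matrix == 1L))
  expect_equal(nrow(s0$truth$events), 0)
  expect_error(sim_presence(h, 10, loss_rate = 0.1, gain_rate = 0.2, seed = 2),
               "loss_rate >= gain_rate")

  s <- sim_presence(h, 1000, loss_rate = 0.05, gain_rate = 0, seed = 31)
  # per-branch losses on the two root-adjacent branches are Binomial(1000, .05)
  ev <- s$truth$events
  tree <- s$truth$tree
  root_children <- tree$nodes$id[!is.na(tree$nodes$parent) &
                                 tree$nodes$parent ==
                                 tree$nodes$id[is.na(tree$nodes$parent)]]
  lo <- qbinom(0.005, 1000, 0.05); hi <- qbinom(0.995, 1000, 0.05)
  for (br in root_children) {
    cnt <- sum(ev$branch == br & ev$type == "loss")
    expect_gte(cnt, lo); expect_lte(cnt, hi)
  }
  # events explain the matrix: replay them along the tree
  nodes <- s$truth$tree$nodes
  for (grp in sample(s$presence$groups, 25)) {
    for (tip in setdiff(s$presence$tips, c("Ga", "Gr"))) {
      path <- tip; cur <- tip
      while (!is.na(nodes$parent[match(cur, nodes$id)])) {
        cur <- nodes$parent[match(cur, nodes$id)]
        path <- c(path, cur)
      }
      state <- 1L
      for (nd in rev(path)) {   # root -> tip
        e <- ev[ev$group == grp & ev$branch == nd, ]
        if (nrow(e)) state <- if (e$type[nrow(e)] == "loss") 0L else 1L
      }
      expect_identical(unname(s$presence$matrix[grp, tip]), state)
    }
  }
})

test_that("sim_ltr_pairs: age zero identical; re-dated ages unbiased", {
  z <- sim_ltr_pairs(3, ages = 0, seed = 4, length_bp = 500)
  expect_identical(z$ltr$five, z$ltr$three)
  expect_error(sim_ltr_pairs(2, ages = 1e5, r = 0, seed = 1), "r must be")
  expect_error(sim_ltr_pairs(2, ages = -1, seed = 1), "ages")

  n <- 300
  s <- sim_ltr_pairs(n, ages = 5e5, seed = 41, length_bp = 2000)
  dates <- date_ltr_set(s$ltr, r = 3.48e-9)
  se <- sd(dates$T_years) / sqrt(n)
  expect_lt(abs(mean(dates$T_years) - 5e5), 3 * se)
})

test_that("sim_recomb_panel plants complete LD blocks and block-conditional marks", {
  s <- sim_recomb_panel(list(n_snps = 200, n_haplotypes = 120,
                             missing_rate = 0),
                        seed = 7)
  inb <- s$truth$snp_block
  idx <- which(inb == 1L)
  # within-block pairs show |D'| = 1 (complete association)
  set.seed(1)
  pairs_checked <- 0
  for (k in seq_len(30)) {
    ij <- sort(sample(idx, 2))
    d <- tryCatch(dprime(s$panel$hap[ij[1], ], s$panel$hap[ij[2], ],
                         n_boot = 20), error = function(e) NULL)
    if (is.null(d)) next      # monomorphic draw
    pairs_checked <- pairs_checked + 1
    expect_equal(d$abs_dprime, 1, tolerance = 1e-12)
  }
  expect_gt(pairs_checked, 10)
  # methylation: cold windows exceed hot windows (CG), alpha = 0.01
  cg <- s$methylation$CG
  mid <- (cg$start + cg$end) / 2
  cold <- rep(FALSE, nrow(cg))
  for (k in seq_len(nrow(s$truth$blocks)))
    cold[mid >= s$truth$blocks$start[k] & mid < s$truth$blocks$end[k]] <- TRUE
  tt <- t.test(cg$value[cold], cg$value[!cold], alternative = "greater")
  expect_lt(tt$p.value, 0.01)
  expect_gt(mean(cg$value[cold]) - mean(cg$value[!cold]), 0)

  # determinism: identical VCF bytes
  s2 <- sim_recomb_panel(list(n_snps = 200, n_haplotypes = 120,
                              missing_rate = 0), seed = 7)
  f1 <- tempfile(fileext = ".vcf"); f2 <- tempfile(fileext = ".vcf")
  write_panel_vcf(s$panel, f1); write_panel_vcf(s2$panel, f2)
  expect_identical(readLines(f1), readLines(f2))

  expect_error(sim_recomb_panel(list(blocks = data.frame(
    start = c(0, 1e6), end = c(2e6, 3e6))), seed = 1), "overlap")
  expect_error(sim_recomb_panel(list(meth_means = list(
    CG = c(cold = 1.2, hot = 0.5))), seed = 1), "\\[0, 1\\]")
})
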