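make_block_panel <- function(n_block = 30, n_free = 30, H = 120, seed = 3) {
  # perfect-phylogeny block followed by independent SNPs
  set.seed(seed)
  sim <- sim_recomb_panel(list(
    n_snps = n_block + n_free, chrom_length = 2e6,
    blocks = data.frame(start = 0, end = 1e6),
    n_haplotypes = H, missing_rate = 0, maf_range = c(0.15, 0.5)),
    seed = seed)
  sim
}

test_that("filter_panel applies strict thresholds", {
  # 10 SNPs: engineer MAF and missingness
  H <- 100
  hap <- matrix(0L, 10, H)
  hap[1, 1:5] <- 1L                 # maf 0.05 exactly -> removed (strict >)
  hap[2, 1:6] <- 1L                 # maf 0.06 -> kept
  hap[3, 1:50] <- 1L                # maf 0.5 -> kept
  hap[4, ] <- 0L                    # monomorphic -> removed
  hap[5, 1:20] <- 1L; hap[5, 91:100] <- NA  # missing 0.10 exactly -> removed
  hap[6, 1:20] <- 1L; hap[6, 92:100] <- NA  # missing 0.09 -> kept
  hap[7, 1:20] <- 1L; hap[7, 80:100] <- NA  # missing 0.21 -> removed
  hap[8, 1:30] <- 1L
  hap[9, 1:40] <- 1L
  hap[10, 1:4] <- 1L                # maf 0.04 -> removed
  panel <- manual_panel(hap, pos = seq(1000, 10000, by = 1000))
  f <- filter_panel(panel)
  expect_setequal(f$pos, c(2000, 3000, 6000, 8000, 9000))  # SNPs 2,3,6,8,9
  expect_false(1000 %in% f$pos)    # MAF exactly 0.05 removed (strict >)
  expect_false(5000 %in% f$pos)    # missing exactly 0.10 removed (strict <)
  expect_true(6000 %in% f$pos)     # missing 0.09 kept
  expect_equal(unname(attr(f, "filter_counts")), c(10, 5))
  expect_error(filter_panel(manual_panel(hap[4, , drop = FALSE], 100)),
               "no SNPs")
})

test_that("D' point estimates: complete LD, independence, formula oracle", {
  # only AB and ab haplotypes -> D' = 1
  a <- c(rep(1, 40), rep(0, 60)); b <- c(rep(1, 40), rep(0, 60))
  expect_equal(dprime(a, b)$dprime, 1)
  # balanced counts -> D' = 0
  expect_equal(dprime(c(25, 25, 25, 25))$dprime, 0)
  expect_error(dprime(c(rep(0, 50)), c(rep(0:1, 25))), "monomorphic")
  expect_error(dprime(c(1, 2, 3)), "counts form")
  set.seed(23)
  for (k in 1:20) {
    cnt <- rmultinom(1, 200, runif(4, 0.05, 1))[, 1]
    got <- dprime(cnt)
    expect_equal(got$dprime, oracle_dprime(cnt[1], cnt[2], cnt[3], cnt[4]),
                 tolerance = 1e-12)
    expect_gte(got$dprime, -1); expect_lte(got$dprime, 1)
  }
  # |D'| = 1 whenever one haplotype class is absent
  for (zero in 1:4) {
    cnt <- c(30, 40, 50, 60); cnt[zero] <- 0
    expect_equal(dprime(cnt)$abs_dprime, 1, tolerance = 1e-12)
  }
  # bootstrap CI is deterministic given the seed
  d1 <- dprime(c(50, 10, 10, 130), seed = 5)
  d2 <- dprime(c(50, 10, 10, 130), seed = 5)
  expect_identical(d1, d2)
})

test_that("block caller recovers a planted block and respects invariants", {
  sim <- make_block_panel(seed = 19)
  panel <- filter_panel(sim$panel)
  blocks <- call_blocks(panel, n_boot = 80, seed = 11)
  expect_s3_class(blocks, "haplotype_blocks")
  expect_true(all(blocks$n_snps >= 2))
  in_block_pos <- panel$pos[panel$pos - 1 < 1e6]
  covered <- sum(vapply(in_block_pos, function(p)
    any(blocks$start < p & blocks$end >= p), logical(1)))
  expect_gte(covered / length(in_block_pos), 0.9)
  # blocks are sorted and non-overlapping
  if (nrow(blocks) > 1)
    expect_true(all(blocks$start[-1] >= blocks$end[-nrow(blocks)]))
})

test_that("two planted blocks separated by a hot interval stay disjoint", {
  set.seed(29)
  sim <- sim_recomb_panel(list(
    n_snps = 90, chrom_length = 3e6, n_haplotypes = 120, missing_rate = 0,
    maf_range = c(0.15, 0.5),
    blocks = data.frame(start = c(0, 2e6), end = c(1e6, 3e6))), seed = 29)
  panel <- filter_panel(sim$panel)
  blocks <- call_blocks(panel, n_boot = 80, seed = 13)
  # no called block spans the hot gap [1e6, 2e6)
  expect_false(any(blocks$start < 1.2e6 & blocks$end > 1.8e6))
  expect_gte(nrow(blocks), 2)
})

test_that("Marey rates: linear, flat and piecewise maps", {
  pos <- seq(5e4, 10e6, by = 5e4)
  lin <- data.frame(chrom = "c1", pos = pos, cM = pos / 1e6)   # 1 cM/Mb
  tr <- marey_rates(lin)
  called <- tr[tr$flag == "", ]
  expect_true(all(abs(called$rate - 1) < 1e-6))
  flat <- data.frame(chrom = "c1", pos = pos, cM = 0)
  tf <- marey_rates(flat)
  expect_true(all(tf$rate[tf$flag == ""] == 0))
  # cold region 20-30 Mb at rate 0; 2 cM/Mb elsewhere
  pos2 <- seq(5e4, 50e6, by = 5e4)
  cm <- 2 * (pmin(pos2, 20e6) + pmax(pos2 - 30e6, 0)) / 1e6
  pw <- data.frame(chrom = "c1", pos = pos2, cM = cm)
  tp <- marey_rates(pw)
  mid <- (tp$start + tp$end) / 2
  cold <- tp$flag == "" & mid > 22e6 & mid < 28e6
  hot <- tp$flag == "" & (mid < 15e6 | mid > 35e6)
  expect_true(all(tp$rate[cold] < 0.5))
  expect_true(all(tp$rate[hot] > 1.5))
  # windows under min_snps are no-calls
  sparse <- data.frame(chrom = "c1",
                       pos = c(seq(1e5, 9e5, 1e5), 5e6 + seq(1e5, 9e5, 1e5)),
                       cM = c(seq(1e5, 9e5, 1e5), 5e6 + seq(1e5, 9e5, 1e5)) / 1e6)
  ts <- marey_rates(sparse)
  expect_true(any(ts$flag == "no_call"))
  expect_true(all(is.na(ts$rate[ts$flag == "no_call"])))
  expect_error(marey_rates(data.frame(chrom = "c", pos = 1:5, cM = 1:5)),
               ">= 10 markers")
})

test_that("window summaries: cold labels, weighted means, strong contacts", {
  blocks <- data.frame(chrom = "c1", start = 0, end = 1e6)
  meth <- list(CG = data.frame(chrom = "c1",
                               start = c(0, 600, 1e6, 1.5e6),
                               end = c(600, 1000, 1.5e6, 2e6),
                               value = c(0.2, 0.8, 0.5, 0.5)))
  contacts <- data.frame(chrom = "c1",
                         start = c(0, 0, 0, 1e6), end = c(1e6, 1e6, 1e6, 2e6),
                         intensity = c(6, 7, 3, 10), distance = c(1, 2, 3, 4))
  w <- summarize_windows(blocks, meth, contacts, window = 1e6,
                         chrom_length = 2e6)
  expect_equal(nrow(w), 2)
  expect_true(w$is_cold[1]); expect_false(w$is_cold[2])
  # weighted mean over {0.2 x 600 bp, 0.8 x 400 bp} = 0.44
  expect_equal(w$meth_CG[1], 0.44)
  expect_equal(w$n_strong_contacts[1], 2L)    # intensities {6,7,3} > 5
  expect_equal(w$n_contacts[1], 3L)
  expect_equal(w$mean_intensity[2], 10)
  expect_error(summarize_windows(blocks, list(CG = transform(
    meth$CG, value = value + 1)), contacts, chrom_length = 2e6), "\\[0, 1\\]")
})

test_that("landscape correlation: planted recovery and degenerate input", {
  set.seed(37)
  sim <- sim_recomb_panel(list(
    n_snps = 10, n_haplotypes = 4, chrom_length = 30e6,
    blocks = data.frame(start = c(2e6, 10e6, 20e6),
                        end = c(6e6, 14e6, 24e6))), seed = 37)
  w <- summarize_windows(sim$truth$blocks, sim$methylation, sim$contacts,
                         chrom_length = 30e6)
  rep <- correlate_landscape(w)
  cg <- rep[rep$variable == "meth_CG", ]
  expect_gt(cg$r, 0)
  expect_lt(cg$p, 1e-3)
  expect_gt(rep$r[rep$variable == "mean_contact_distance"], 0)
  expect_lt(rep$r[rep$variable == "mean_intensity"], 0)
  # constant methylation -> r undefined (NA)
  w2 <- w
  w2$meth_CG <- 0.5
  rep2 <- correlate_landscape(w2)
  expect_true(is.na(rep2$r[rep2$variable == "meth_CG"]))
  expect_error(correlate_landscape(w[w$is_cold, ]), "both")
  expect_error(correlate_landscape(w[1:5, ]), ">= 10")
})
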