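# -- synthetic data with planted ground truth ---------------------------------
#
# Every input the analysis stages consume can be generated here: codon
# alignments evolved on the dated history, ortholog presence/absence with
# branch-specific losses/gains, LTR pairs diverged since a drawn insertion
# age, TE families, and a phased SNP panel with planted low-recombination
# blocks whose windows carry elevated methylation and many-but-weak
# long-range contacts.
#
# Reproducibility: one root seed; gene/element k uses the derived stream
# seed (seed + 77003 * k) mod (2^31 - 1), so any record is reproducible in
# isolation.

stream_seed <- function(seed, k) {
  s <- (as.double(seed) + 77003 * as.double(k)) %% 2147483646
  as.integer(s) + 1L
}

require_seed <- function(seed) {
  if (missing(seed) || is.null(seed) || !is.finite(seed))
    stop("a seed is required for reproducible simulation")
  as.integer(seed)
}

# exact Jukes-Cantor site evolution of an integer nt vector for expected
# b substitutions/site (vectorized; used for non-coding sequence)
evolve_jc <- function(x, b) {
  p_change <- 0.75 * (1 - exp(-4 * b / 3))
  hit <- runif(length(x)) < p_change
  n <- sum(hit)
  if (n) x[hit] <- (x[hit] + sample.int(3, n, replace = TRUE)) %% 4L
  x
}

# codon-context evolution: proposals arrive as a Poisson process with
# intensity b per nucleotide position (JC proposal kernel); synonymous
# proposals are accepted, nonsynonymous with probability omega, proposals
# creating a stop codon are rejected.  The realized synonymous rate per NG86
# synonymous site therefore equals the proposal intensity, so synonymous
# divergence obeys the molecular clock exactly.
evolve_codon_edge <- function(x, b, omega, tab) {
  L <- length(x)
  n <- rpois(1, b * L)
  if (n == 0) return(x)
  pos <- sample.int(L, n, replace = TRUE)
  alt <- sample.int(3, n, replace = TRUE)
  u <- runif(n)
  for (i in seq_len(n)) {
    p <- pos[i]
    newb <- (x[p] + alt[i]) %% 4L
    i0 <- ((p - 1L) %/% 3L) * 3L
    c1 <- x[i0 + 1L]; c2 <- x[i0 + 2L]; c3 <- x[i0 + 3L]
    old_cod <- 16L * c1 + 4L * c2 + c3 + 1L
    within <- p - i0
    new_cod <- old_cod + (newb - x[p]) * c(16L, 4L, 1L)[within]
    if (tab$is_stop[new_cod]) next
    if (tab$aa[new_cod] == tab$aa[old_cod] || u[i] < omega) x[p] <- newb
  }
  x
}

resolve_per_record <- function(spec, n, what) {
  v <- if (is.function(spec)) spec(n)
  else if (length(spec) == 1) rep(spec, n)
  else if (length(spec) == n) spec
  else stop(what, " must be a scalar, a length-n vector, or a function(n)")
  as.numeric(v)
}

#' Simulate per-gene codon alignments on a species history
#'
#' Codon sites evolve by a Jukes-Cantor nucleotide proposal process whose
#' proposals are accepted with probability 1 if synonymous and `omega` if
#' nonsynonymous; stop-creating changes are rejected, so alignments are free
#' of internal stop codons.  The proposal intensity on each branch equals the
#' branch's expected substitutions per site
#' (`clock_rate * years * multiplier`), which makes the realized synonymous
#' divergence of a tip pair equal `2 r T` in expectation.
#'
#' @param history A `species_history` from [make_history()].
#' @param n_genes Number of genes.
#' @param n_codons Codons per gene (>= 10).
#' @param omega Per-gene dN/dS: scalar, length-`n_genes` vector, or
#'   `function(n)`; all values must be > 0.
#' @param seed Integer root seed (required).
#' @param gap_rate Per-column probability that the column is gapped in one
#'   randomly chosen taxon (default 0).
#' @param taxa Optional tip subset; the history is pruned to these tips.
#' @return A list with components `alignments` (an `alignment_set`) and
#'   `truth` (a `sim_truth` holding per-gene omega, stream seeds and the
#'   expected per-branch substitutions/site).
#' @export
sim_alignments <- function(history, n_genes, n_codons, omega = 1, seed,
                           gap_rate = 0, taxa = NULL) {
  seed <- require_seed(seed)
  if (n_codons < 10) stop("n_codons must be >= 10")
  if (!is.null(taxa)) history <- prune_history(history, taxa)
  omega <- resolve_per_record(omega, n_genes, "omega")
  if (any(omega <= 0)) stop("omega values must be > 0")
  if (gap_rate < 0 || gap_rate >= 1) stop("gap_rate must be in [0, 1)")

  tab <- codon_tables()
  b <- branch_expected_subs(history)
  nodes <- history$nodes
  # preorder over branches (parents before children)
  ord <- character(0)
  frontier <- nodes$id[is.na(nodes$parent)]
  while (length(frontier)) {
    nxt <- nodes$id[!is.na(nodes$parent) & nodes$parent %in% frontier]
    ord <- c(ord, nxt)
    frontier <- nxt
  }
  tips <- history$tips$tip
  L <- 3L * n_codons
  gene_ids <- sprintf("gene%04d", seq_len(n_genes))
  genes <- vector("list", n_genes)
  seeds <- integer(n_genes)
  for (g in seq_len(n_genes)) {
    seeds[g] <- stream_seed(seed, g)
    set.seed(seeds[g])
    root <- as.integer(t(tab$digits[sample(tab$sense, n_codons, replace = TRUE), ]))
    seqs <- list()
    seqs[[nodes$id[is.na(nodes$parent)]]] <- root
    for (v in ord)
      seqs[[v]] <- evolve_codon_edge(seqs[[nodes$parent[match(v, nodes$id)]]],
                                     b[[v]], omega[g], tab)
    out <- vapply(tips, function(tp) int_to_nt(seqs[[tp]]), character(1))
    if (gap_rate > 0) {
      cols <- which(runif(L) < gap_rate)
      if (length(cols)) {
        who <- sample.int(length(tips), length(cols), replace = TRUE)
        for (j in seq_along(cols))
          substr(out[who[j]], cols[j], cols[j]) <- "-"
      }
    }
    genes[[g]] <- out
  }
  names(genes) <- gene_ids
  aln <- structure(list(genes = genes, tips = history$tips,
                        n_codons = n_codons), class = "alignment_set")
  truth <- structure(list(
    kind = "alignments",
    genes = data.frame(gene = gene_ids, omega = omega, stream_seed = seeds,
                       stringsAsFactors = FALSE),
    branch_subs = as.list(b),
    clock_rate = history$clock_rate
  ), class = "sim_truth")
  list(alignments = aln, truth = truth)
}

#' @export
print.alignment_set <- function(x, ...) {
  cat("alignment_set:", length(x$genes), "genes x", nrow(x$tips), "taxa,",
      x$n_codons, "codons\n")
  invisible(x)
}

#' Simulate an ortholog presence/absence matrix with branch losses and gains
#'
#' Events occur on the phylogeny of the ten subgenome tips (the history
#' pruned to the At and Dt tips); the two diploid progenitors are recorded as
#' always present, matching the diploid-anchored filter of the gene-flux
#' stage.  On each branch a present group is lost with probability
#' `loss_rate` and an absent group regained with probability `gain_rate`.
#'
#' @param history A `species_history`.
#' @param n_groups Number of ortholog groups.
#' @param loss_rate,gain_rate Per-branch event probabilities with
#'   `loss_rate >= gain_rate >= 0`.
#' @param seed Integer seed.
#' @return List with `presence` (a `presence_matrix`: groups x (2 diploids +
#'   10 subgenome tips) binary matrix) and `truth` (`sim_truth` with the
#'   per-event branch placements).
#' @export
sim_presence <- function(history, n_groups, loss_rate, gain_rate = 0, seed) {
  seed <- require_seed(seed)
  if (gain_rate < 0 || loss_rate < gain_rate)
    stop("rates must satisfy loss_rate >= gain_rate >= 0")
  sub_tips <- history$tips$tip[history$tips$subgenome %in% c("At", "Dt")]
  sub <- prune_history(history, sub_tips)
  nodes <- sub$nodes
  ord <- character(0)
  frontier <- nodes$id[is.na(nodes$parent)]
  while (length(frontier)) {
    nxt <- nodes$id[!is.na(nodes$parent) & nodes$parent %in% frontier]
    ord <- c(ord, nxt)
    frontier <- nxt
  }
  set.seed(seed)
  state <- matrix(1L, n_groups, nrow(nodes), dimnames = list(NULL, nodes$id))
  events <- list()
  for (v in ord) {
    par <- nodes$parent[match(v, nodes$id)]
    u <- runif(n_groups)
    lost <- state[, par] == 1L & u < loss_rate
    gained <- state[, par] == 0L & u < gain_rate
    state[, v] <- state[, par]
    state[lost, v] <- 0L
    state[gained, v] <- 1L
    if (any(lost)) events[[length(events) + 1]] <-
      data.frame(group = which(lost), branch = v, type = "loss")
    if (any(gained)) events[[length(events) + 1]] <-
      data.frame(group = which(gained), branch = v, type = "gain")
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(group = integer(0), branch = character(0), type = character(0))
  group_ids <- sprintf("grp%05d", seq_len(n_groups))
  mat <- cbind(Ga = 1L, Gr = 1L, state[, sub_tips, drop = FALSE])
  rownames(mat) <- group_ids
  events$group <- group_ids[events$group]
  pm <- structure(list(matrix = mat, tips = colnames(mat), groups = group_ids),
                  class = "presence_matrix")
  truth <- structure(list(kind = "presence", events = events,
                          loss_rate = loss_rate, gain_rate = gain_rate,
                          tree = sub), class = "sim_truth")
  list(presence = pm, truth = truth)
}

#' Simulate LTR retrotransposon pairs diverged since insertion
#'
#' The two terminal repeats of an element are identical at insertion; each
#' then accumulates `r * age` expected substitutions per site (Jukes-Cantor),
#' so the pair diverges by `2 r age`.
#'
#' @param n Number of elements.
#' @param ages Insertion ages in years: scalar, length-`n` vector, or
#'   `function(n)`.
#' @param r Substitution rate per site per year (> 0), default `3.48e-9`.
#' @param seed Integer seed.
#' @param length_bp LTR length in bp (default 2000).
#' @return List with `ltr` (an `ltr_pair_set`) and `truth` (ages).
#' @export
sim_ltr_pairs <- function(n, ages, r = 3.48e-9, seed, length_bp = 2000) {
  seed <- require_seed(seed)
  if (r <= 0) stop("r must be > 0")
  ages <- resolve_per_record(ages, n, "ages")
  if (any(ages < 0)) stop("ages must be >= 0")
  ids <- sprintf("ltr%04d", seq_len(n))
  five <- three <- character(n)
  for (i in seq_len(n)) {
    set.seed(stream_seed(seed, i))
    anc <- sample(0:3, length_bp, replace = TRUE)
    b <- r * ages[i]
    five[i] <- int_to_nt(evolve_jc(anc, b))
    three[i] <- int_to_nt(evolve_jc(anc, b))
  }
  ltr <- structure(list(id = ids, five = five, three = three, r = r),
                   class = "ltr_pair_set")
  truth <- structure(list(kind = "ltr", ages = setNames(ages, ids), r = r),
                     class = "sim_truth")
  list(ltr = ltr, truth = truth)
}

#' Simulate labeled TE families across genomes
#'
#' Plants `n_shared` families whose members come from several genomes and
#' `n_specific` families confined to one genome; members diverge from the
#' family ancestor so that expected within-family identity is
#' `within_identity`.  Used to exercise the TE clustering and sharedness
#' classification.
#'
#' @param n_shared,n_specific Family counts.
#' @param members_per_family Members per family.
#' @param genomes Genome labels to draw from.
#' @param length_bp Element length.
#' @param within_identity Expected pairwise identity within a family.
#' @param seed Integer seed.
#' @return List with `te` (data.frame `id`, `genome`, `seq`) and `truth`
#'   (family assignment and type).
#' @export
sim_te_families <- function(n_shared, n_specific, members_per_family = 10,
                            genomes = c("Ga", "Gr", "Gh_At", "Gh_Dt"),
                            length_bp = 1000, within_identity = 0.95, seed) {
  seed <- require_seed(seed)
  if (within_identity <= 0.5 || within_identity > 1)
    stop("within_identity must be in (0.5, 1]")
  d <- -0.75 * log(1 - 4 * (1 - within_identity) / 2 / 3) # per-branch JC dist
  nfam <- n_shared + n_specific
  rows <- list()
  fam_type <- rep(c("shared", "specific"), c(n_shared, n_specific))
  for (f in seq_len(nfam)) {
    set.seed(stream_seed(seed, f))
    anc <- sample(0:3, length_bp, replace = TRUE)
    g <- if (fam_type[f] == "shared")
      sample(genomes, members_per_family, replace = TRUE) else
      rep(sample(genomes, 1), members_per_family)
    if (fam_type[f] == "shared" && length(unique(g)) == 1)   # force sharing
      g[1] <- sample(setdiff(genomes, g[1]), 1)
    seqs <- vapply(seq_len(members_per_family),
                   function(i) int_to_nt(evolve_jc(anc, d)), character(1))
    rows[[f]] <- data.frame(
      id = sprintf("fam%03d_m%02d", f, seq_len(members_per_family)),
      genome = g, seq = seqs, family = sprintf("fam%03d", f),
      type = fam_type[f], stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  list(te = all[, c("id", "genome", "seq")],
       truth = structure(list(kind = "te",
                              families = all[, c("id", "family", "type")]),
                         class = "sim_truth"))
}

#' Default configuration for [sim_recomb_panel()]
#'
#' @return Named list of panel parameters; any subset can be overridden via
#'   the `config` argument of [sim_recomb_panel()].
#' @export
recomb_panel_config <- function() {
  list(
    chrom = "chr1",
    chrom_length = 10e6,
    n_snps = 1000,
    n_haplotypes = 200,
    blocks = data.frame(start = c(2e6, 6e6), end = c(3.5e6, 7.5e6)),
    n_founders = 6,
    within_block_recomb = 0,
    background_rate_cM_Mb = 2,
    maf_range = c(0.02, 0.5),
    missing_rate = 0.02,
    meth_window = 1000,
    meth_means = list(CG = c(cold = 0.80, hot = 0.55),
                      CHG = c(cold = 0.60, hot = 0.35),
                      CHH = c(cold = 0.15, hot = 0.08)),
    meth_concentration = 50,
    contact_window = 1e6,
    contacts_mean = c(cold = 60, hot = 20),
    intensity_mean = c(cold = 4, hot = 7),
    intensity_shape = 3,
    distance_mean = c(cold = 5e6, hot = 1e6)
  )
}

# founder haplotypes under a perfect phylogeny (infinite sites): every SNP
# marks one clade of a random founder genealogy, so any SNP pair shows at
# most three gametes and |D'| = 1 among founders.
founder_clades <- function(n_founders) {
  sets <- list(seq_len(n_founders))
  queue <- list(seq_len(n_founders))
  while (length(queue)) {
    s <- queue[[1]]; queue <- queue[-1]
    if (length(s) < 2) next
    k <- sample(seq_len(length(s) - 1), 1)
    left <- sort(sample(s, k)); right <- setdiff(s, left)
    sets <- c(sets, list(left), list(right))
    queue <- c(queue, list(left), list(right))
  }
  # drop the trivial full set; keep clades of size 1..n-1
  Filter(function(s) length(s) < n_founders, sets)
}

#' Simulate a phased SNP panel with planted recombination cold spots
#'
#' Haplotypes are mosaics: inside each planted block every haplotype carries
#' one of `n_founders` founder haplotypes generated under a perfect phylogeny
#' (so within-block SNP pairs are in complete association when
#' `within_block_recomb = 0`); outside blocks SNPs segregate independently
#' (free recombination).  Per-window methylation (CG/CHG/CHH) is drawn with
#' block-conditional means, and chromatin-contact records give block windows
#' more but weaker, longer-range contacts.  A Marey genetic map accumulates
#' `background_rate_cM_Mb` outside blocks and 0 inside.
#'
#' @param config Named list overriding [recomb_panel_config()] entries.
#' @param seed Integer seed.
#' @return List with `panel` (a `genotype_panel`), `map_points`,
#'   `methylation` (list of bedGraph-like data.frames per context),
#'   `contacts` (per-contact records), and `truth`.
#' @export
sim_recomb_panel <- function(config = list(), seed) {
  seed <- require_seed(seed)
  cfg <- recomb_panel_config()
  bad <- setdiff(names(config), names(cfg))
  if (length(bad)) stop("unknown config key(s): ", paste(bad, collapse = ", "))
  cfg[names(config)] <- config
  blocks <- cfg$blocks[order(cfg$blocks$start), , drop = FALSE]
  if (nrow(blocks) > 1 &&
      any(blocks$start[-1] < blocks$end[-nrow(blocks)]))
    stop("planted blocks overlap")
  for (ctx in names(cfg$meth_means))
    if (any(cfg$meth_means[[ctx]] < 0 | cfg$meth_means[[ctx]] > 1))
      stop("methylation means must be in [0, 1]")
  if (cfg$n_haplotypes %% 2 != 0) stop("n_haplotypes must be even")

  set.seed(seed)
  pos <- sort(sample.int(cfg$chrom_length, cfg$n_snps))
  in_block <- rep(0L, cfg$n_snps)            # 0 = hot, k = block k
  for (k in seq_len(nrow(blocks)))
    in_block[pos - 1 >= blocks$start[k] & pos - 1 < blocks$end[k]] <- k

  H <- cfg$n_haplotypes
  hap <- matrix(0L, cfg$n_snps, H)
  founder_of <- matrix(NA_integer_, nrow(blocks), H)
  for (k in seq_len(nrow(blocks))) {
    idx <- which(in_block == k)
    if (!length(idx)) next
    clades <- founder_clades(cfg$n_founders)
    fhap <- vapply(idx, function(i) {
      cl <- clades[[sample.int(length(clades), 1)]]
      as.integer(seq_len(cfg$n_founders) %in% cl)
    }, integer(cfg$n_founders))              # founders x snps-in-block
    z <- sample.int(cfg$n_founders, H, replace = TRUE)
    founder_of[k, ] <- z
    for (j in seq_along(idx)) {
      if (cfg$within_block_recomb > 0 && j > 1) {
        sw <- runif(H) < cfg$within_block_recomb
        if (any(sw)) z[sw] <- sample.int(cfg$n_founders, sum(sw), replace = TRUE)
      }
      hap[idx[j], ] <- t(fhap)[j, z]
    }
  }
  hot <- which(in_block == 0L)
  if (length(hot)) {
    p <- runif(length(hot), cfg$maf_range[1], cfg$maf_range[2])
    hap[hot, ] <- matrix(rbinom(length(hot) * H, 1, rep(p, H)),
                         nrow = length(hot))
  }
  if (cfg$missing_rate > 0) {
    miss <- matrix(runif(cfg$n_snps * H) < cfg$missing_rate, cfg$n_snps, H)
    hap[miss] <- NA_integer_
  }
  samples <- sprintf("S%03d", seq_len(H / 2))
  panel <- structure(list(chrom = rep(cfg$chrom, cfg$n_snps), pos = pos,
                          hap = hap, samples = samples),
                     class = "genotype_panel")

  # Marey map: cM accumulates only outside blocks
  hot_bp_before <- function(x) {
    inb <- vapply(seq_len(nrow(blocks)), function(k)
      pmax(0, pmin(x, blocks$end[k]) - blocks$start[k]), numeric(length(x)))
    x - if (is.matrix(inb)) rowSums(inb) else sum(inb)
  }
  map_points <- data.frame(chrom = cfg$chrom, pos = pos,
                           cM = cfg$background_rate_cM_Mb *
                             hot_bp_before(pos) / 1e6)

  # methylation tracks per context over meth_window bp windows
  wstart <- seq(0, cfg$chrom_length - 1, by = cfg$meth_window)
  wend <- pmin(wstart + cfg$meth_window, cfg$chrom_length)
  wmid <- (wstart + wend) / 2
  wcold <- rep(FALSE, length(wstart))
  for (k in seq_len(nrow(blocks)))
    wcold[wmid >= blocks$start[k] & wmid < blocks$end[k]] <- TRUE
  conc <- cfg$meth_concentration
  methylation <- lapply(cfg$meth_means, function(mm) {
    mu <- ifelse(wcold, mm["cold"], mm["hot"])
    data.frame(chrom = cfg$chrom, start = wstart, end = wend,
               value = rbeta(length(mu), mu * conc, (1 - mu) * conc))
  })

  # per-contact records for contact_window analysis windows
  cstart <- seq(0, cfg$chrom_length - 1, by = cfg$contact_window)
  cend <- pmin(cstart + cfg$contact_window, cfg$chrom_length)
  ccold <- vapply(seq_along(cstart), function(i) {
    ov <- sum(pmax(0, pmin(cend[i], blocks$end) - pmax(cstart[i], blocks$start)))
    ov > 0.5 * (cend[i] - cstart[i])
  }, logical(1))
  contacts <- do.call(rbind, lapply(seq_along(cstart), function(i) {
    cls <- if (ccold[i]) "cold" else "hot"
    n <- rpois(1, cfg$contacts_mean[cls])
    if (n == 0) return(NULL)
    data.frame(chrom = cfg$chrom, start = cstart[i], end = cend[i],
               intensity = rgamma(n, shape = cfg$intensity_shape,
                                  scale = cfg$intensity_mean[cls] /
                                    cfg$intensity_shape),
               distance = rexp(n, 1 / cfg$distance_mean[cls]))
  }))

  truth <- structure(list(
    kind = "recomb_panel", config = cfg, blocks = blocks,
    snp_block = in_block, founder_of = founder_of,
    window_cold = data.frame(start = cstart, end = cend, cold = ccold)
  ), class = "sim_truth")
  list(panel = panel, map_points = map_points, methylation = methylation,
       contacts = contacts, truth = truth)
}

#' @export
print.genotype_panel <- function(x, ...) {
  cat("genotype_panel:", length(x$pos), "SNPs x", ncol(x$hap),
      "haplotypes (", length(x$samples), "samples )\n")
  invisible(x)
}

#' Per-SNP minor allele frequency and missing rate
#'
#' @param panel A `genotype_panel`.
#' @return data.frame with `chrom`, `pos`, `maf`, `missing`.
#' @export
panel_stats <- function(panel) {
  n_ok <- rowSums(!is.na(panel$hap))
  f <- rowSums(panel$hap == 1L, na.rm = TRUE) / pmax(n_ok, 1)
  data.frame(chrom = panel$chrom, pos = panel$pos,
             maf = pmin(f, 1 - f),
             missing = rowSums(is.na(panel$hap)) / ncol(panel$hap))
}
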