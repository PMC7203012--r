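# -- pipeline orchestration ------------------------------------------------------

#' Default pipeline configuration
#'
#' All thresholds carry their field defaults: clock rate `r = 3.48e-9`
#' substitutions/site/year, TE identity 0.90, D' upper bound 0.90, Marey span
#' 7.5%, 1-Mb analysis windows, MAF > 0.05 and missingness < 0.10 filters,
#' strong-contact intensity threshold 5.
#'
#' @return Nested named list; any subset may be overridden via the `config`
#'   argument of [run_pipeline()] (unknown keys are rejected).
#' @export
default_pipeline_config <- function() {
  list(
    seed = 1,
    outdir = file.path(tempdir(), "polyrate_out"),
    stages = list(simulate = TRUE, divergence = TRUE, rates = TRUE,
                  date = TRUE, compose = TRUE, flux = TRUE, recomb = TRUE),
    history = list(split_times = NULL, clock_rate = 3.48e-9,
                   multipliers = NULL),
    simulate = list(n_genes = 60, n_codons = 100, omega = 1, gap_rate = 0,
                    n_groups = 300, loss_rate = 0.05, gain_rate = 0.01,
                    n_ltr = 40, ltr_age = 5e5, ltr_length = 1000,
                    te_shared = 5, te_specific = 5, te_length = 300,
                    panel = utils::modifyList(recomb_panel_config(),
                                              list(n_snps = 300,
                                                   n_haplotypes = 100))),
    params = list(r = 3.48e-9, identity_threshold = 0.90,
                  dprime_upper = 0.90, dprime_lower = 0.70,
                  span_fraction = 0.075, window = 1e6,
                  maf_min = 0.05, missing_max = 0.10,
                  strong_threshold = 5, kmer_k = 20, alpha = 0.05,
                  loss_weight = 1, gain_weight = 2, summary = "mean")
  )
}

merge_config <- function(defaults, config, path = "") {
  bad <- setdiff(names(config), names(defaults))
  if (length(bad))
    stop("unknown config key(s): ",
         paste(paste0(path, bad), collapse = ", "))
  for (k in names(config)) {
    if (is.list(defaults[[k]]) && is.list(config[[k]]) &&
        !is.data.frame(defaults[[k]]) && !is.data.frame(config[[k]]) &&
        !is.null(names(defaults[[k]])) && k != "history")
      defaults[[k]] <- merge_config(defaults[[k]], config[[k]],
                                    paste0(path, k, "$"))
    else defaults[k] <- list(config[[k]])
  }
  defaults
}

#' Read a pipeline configuration from a JSON file
#'
#' @param path JSON file with any subset of [default_pipeline_config()] keys.
#' @return Configuration list.
#' @export
read_pipeline_config <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}

#' Run the simulate-then-analyze pipeline
#'
#' Executes the enabled stages in dependency order (simulate, divergence,
#' rates, date, compose, flux, recomb), writes per-stage outputs and fixtures
#' under `outdir`, and returns (and writes as `report.json`) a
#' machine-readable report with the resolved configuration, seeds, record
#' counts and headline statistics.  Reruns with the same config and seed
#' produce an identical report.
#'
#' @param config Named list overriding [default_pipeline_config()] entries;
#'   unknown keys are rejected.
#' @return The report, invisibly.
#' @export
run_pipeline <- function(config = list()) {
  cfg <- merge_config(default_pipeline_config(), config)
  dir.create(cfg$outdir, showWarnings = FALSE, recursive = TRUE)
  p <- cfg$params
  on <- function(s) isTRUE(cfg$stages[[s]])
  report <- list(package = "polyrate",
                 version = as.character(packageVersion("polyrate")),
                 seed = cfg$seed, config = cfg, stages = list())
  sims <- NULL
  history <- make_history(split_times = cfg$history$split_times,
                          clock_rate = cfg$history$clock_rate,
                          multipliers = cfg$history$multipliers)

  if (on("simulate")) {
    sc <- cfg$simulate
    aln <- sim_alignments(history, sc$n_genes, sc$n_codons, omega = sc$omega,
                          seed = cfg$seed, gap_rate = sc$gap_rate)
    pres <- sim_presence(history, sc$n_groups, sc$loss_rate, sc$gain_rate,
                         seed = cfg$seed + 1)
    ltr <- sim_ltr_pairs(sc$n_ltr, ages = sc$ltr_age, r = p$r,
                         seed = cfg$seed + 2, length_bp = sc$ltr_length)
    te <- sim_te_families(sc$te_shared, sc$te_specific,
                          length_bp = sc$te_length, seed = cfg$seed + 3)
    pan <- sim_recomb_panel(sc$panel, seed = cfg$seed + 4)
    write_fixtures(list(alignments = aln$alignments, history = history,
                        presence = pres$presence, ltr = ltr$ltr,
                        panel = pan$panel, map_points = pan$map_points,
                        methylation = pan$methylation,
                        contacts = pan$contacts, te = te$te,
                        truth = list(aln$truth, pres$truth, ltr$truth,
                                     te$truth, pan$truth)),
                   file.path(cfg$outdir, "fixtures"))
    sims <- list(aln = aln, pres = pres, ltr = ltr, te = te, pan = pan)
    report$stages$simulate <- list(
      n_genes = length(aln$alignments$genes),
      n_groups = length(pres$presence$groups),
      n_ltr = length(ltr$ltr$id), n_te = nrow(te$te),
      n_snps = length(pan$panel$pos))
  }
  need_sims <- function(stage) {
    if (is.null(sims))
      stop("stage '", stage, "' is enabled but the simulate stage is off ",
           "and no inputs are available")
    sims
  }

  species <- c("Gh", "Gb", "Gt", "Gm", "Gd")
  pdist <- NULL
  if (on("divergence")) {
    s <- need_sims("divergence")
    pairs <- c(lapply(species, function(sp) c(paste0(sp, "_At"), "Ga")),
               lapply(species, function(sp) c(paste0(sp, "_Dt"), "Gr")))
    pdist <- pdistance_table(s$aln$alignments, pairs)
    data.table::fwrite(pdist, file.path(cfg$outdir, "pdistance.tsv"),
                       sep = "\t")
    kk <- kaks_table(s$aln$alignments,
                     lapply(species, function(sp)
                       c(paste0(sp, "_At"), paste0(sp, "_Dt"))))
    data.table::fwrite(kk, file.path(cfg$outdir, "kaks.tsv"), sep = "\t")
    tot <- count_substitution_totals(s$aln$alignments, c("Gh_At", "Gh_Dt"))
    report$stages$divergence <- list(
      n_pdist = nrow(pdist), n_kaks = nrow(kk),
      positively_selected = sum(kk$ratio > 1, na.rm = TRUE),
      totals_example = list(pair = tot$pair,
                            differences = tot$total_differences,
                            sites = tot$total_sites))
  }
  if (on("rates")) {
    if (is.null(pdist)) stop("rates stage requires the divergence stage")
    tests <- do.call(rbind, lapply(species, function(sp)
      subgenome_rate_test(pdist, sp, alpha = p$alpha,
                          family_size = length(species))))
    data.table::fwrite(tests, file.path(cfg$outdir, "tests.tsv"), sep = "\t")
    cls <- classify_gene_rate_shifts(need_sims("rates")$aln$alignments, "Gh",
                                     alpha = p$alpha)
    data.table::fwrite(cls, file.path(cfg$outdir, "gene_classes.tsv"),
                       sep = "\t")
    report$stages$rates <- list(
      n_tests = nrow(tests),
      significant = sum(tests$p_adjusted <= p$alpha),
      gene_classes = as.list(table(cls$class)))
  }
  if (on("date")) {
    s <- need_sims("date")
    est1 <- date_species_pair(s$aln$alignments, c("Gm_At", "Gh_At"),
                              r = p$r, summary = p$summary)
    est2 <- date_species_pair(s$aln$alignments, c("Gb_At", "Gd_At"),
                              r = p$r, summary = p$summary)
    ltr_dates <- date_ltr_set(s$ltr$ltr, r = p$r)
    data.table::fwrite(ltr_dates, file.path(cfg$outdir, "ltr_dates.tsv"),
                       sep = "\t")
    report$stages$date <- list(
      gm_vs_gh_years = est1$T_years, gb_vs_gd_years = est2$T_years,
      ltr_mean_age_years = mean(ltr_dates$T_years, na.rm = TRUE),
      ltr_saturated = sum(ltr_dates$flag == "saturated"))
  }
  if (on("compose")) {
    s <- need_sims("compose")
    cl <- cluster_te_sequences(s$te$te, threshold = p$identity_threshold)
    sharing <- classify_cluster_sharing(cl)
    data.table::fwrite(sharing$table, file.path(cfg$outdir, "te_clusters.tsv"),
                       sep = "\t")
    by_genome <- split(s$te$te$seq, s$te$te$genome)
    spectra <- lapply(by_genome, kmer_spectrum, k = p$kmer_k)
    curve <- cumulative_curve(spectra)
    data.table::fwrite(curve, file.path(cfg$outdir, "kmer_curve.tsv"),
                       sep = "\t")
    report$stages$compose <- list(
      n_clusters = length(cl$clusters),
      shared = sum(sharing$table$class == "shared"),
      specific = sum(sharing$table$class == "specific"))
  }
  if (on("flux")) {
    s <- need_sims("flux")
    tab <- data.frame(group = s$pres$presence$groups, s$pres$presence$matrix,
                      check.names = FALSE)
    sub_tips <- setdiff(s$pres$presence$tips, c("Ga", "Gr"))
    pm <- build_presence_matrix(tab, "Ga", "Gr", sub_tips)
    flux <- parsimony_flux(pm, subgenome_tree(history),
                           loss_weight = p$loss_weight,
                           gain_weight = p$gain_weight)
    data.table::fwrite(flux$branches, file.path(cfg$outdir, "flux.tsv"),
                       sep = "\t")
    report$stages$flux <- list(
      groups_evaluated = length(pm$groups),
      losses = sum(flux$branches$losses), gains = sum(flux$branches$gains),
      total_cost = flux$total_cost)
  }
  if (on("recomb")) {
    s <- need_sims("recomb")
    pan <- filter_panel(s$pan$panel, p$maf_min, p$missing_max)
    blocks <- call_blocks(pan, dprime_upper_min = p$dprime_upper,
                          dprime_lower_min = p$dprime_lower,
                          seed = cfg$seed + 5)
    data.table::fwrite(blocks, file.path(cfg$outdir, "blocks.bed"),
                       sep = "\t", col.names = FALSE)
    marey <- marey_rates(s$pan$map_points, span_fraction = p$span_fraction,
                         window = p$window)
    data.table::fwrite(marey, file.path(cfg$outdir, "marey.tsv"), sep = "\t")
    wins <- summarize_windows(blocks, s$pan$methylation, s$pan$contacts,
                              strong_threshold = p$strong_threshold,
                              window = p$window,
                              chrom_length = s$pan$truth$config$chrom_length)
    corr <- correlate_landscape(wins)
    data.table::fwrite(wins, file.path(cfg$outdir, "windows.tsv"), sep = "\t")
    data.table::fwrite(corr, file.path(cfg$outdir, "correlations.tsv"),
                       sep = "\t")
    report$stages$recomb <- list(
      snps_after_filter = length(pan$pos), n_blocks = nrow(blocks),
      marey_windows = nrow(marey),
      meth_CG_r = corr$r[corr$variable == "meth_CG"],
      n_strong_r = corr$r[corr$variable == "n_strong_contacts"])
  }
  jsonlite::write_json(report, file.path(cfg$outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE,
                       null = "null", pretty = TRUE)
  invisible(report)
}

#' Validate fixture files without running the pipeline
#'
#' Format checks with line-level diagnostics: per-gene FASTA alignments must
#' have equal-length records, Newick files must parse, VCF genotypes must be
#' phased with sorted positions, and tracks must be coordinate-sorted.
#'
#' @param paths Named list with any of `alignments` (directory), `history`
#'   (Newick file), `vcf`, `tracks` (character vector of bedGraph-dialect
#'   TSVs).
#' @return data.frame with columns `file`, `line`, `problem`; zero rows when
#'   everything is clean.
#' @export
validate_inputs <- function(paths) {
  fail <- list()
  note <- function(file, line, problem)
    fail[[length(fail) + 1]] <<- data.frame(file = file, line = line,
                                            problem = problem)
  if (!is.null(paths$alignments)) {
    for (f in list.files(paths$alignments, pattern = "\\.fasta$",
                         full.names = TRUE)) {
      x <- tryCatch(Biostrings::readDNAStringSet(f), error = function(e) NULL)
      if (is.null(x)) note(f, NA, "unreadable FASTA")
      else if (length(unique(Biostrings::width(x))) != 1)
        note(f, NA, "unequal alignment lengths")
    }
  }
  if (!is.null(paths$history)) {
    ok <- tryCatch({ read_history_newick(paths$history); TRUE },
                   error = function(e) FALSE)
    if (!ok) note(paths$history, 1, "Newick parse failure")
  }
  if (!is.null(paths$vcf)) {
    lines <- readLines(paths$vcf)
    body <- which(!startsWith(lines, "#"))
    last_pos <- -Inf; last_chrom <- ""
    for (i in body) {
      fld <- strsplit(lines[i], "\t")[[1]]
      if (length(fld) < 10) { note(paths$vcf, i, "too few columns"); next }
      if (any(grepl("/", fld[-(1:9)], fixed = TRUE)))
        note(paths$vcf, i, "unphased genotype")
      pos <- as.numeric(fld[2])
      if (fld[1] == last_chrom && pos <= last_pos)
        note(paths$vcf, i, "positions not strictly increasing")
      last_pos <- pos; last_chrom <- fld[1]
    }
  }
  for (tr in paths$tracks %||% character(0)) {
    lines <- readLines(tr)
    last <- c("", -Inf)
    for (i in seq_along(lines)) {
      fld <- strsplit(lines[i], "\t")[[1]]
      if (length(fld) < 4) { note(tr, i, "too few columns"); next }
      st <- as.numeric(fld[2]); en <- as.numeric(fld[3])
      if (is.na(st) || is.na(en) || en < st)
        note(tr, i, "bad interval")
      else if (fld[1] == last[1] && st < as.numeric(last[2]))
        note(tr, i, "track not sorted")
      last <- c(fld[1], st)
    }
  }
  if (!length(fail))
    return(data.frame(file = character(0), line = numeric(0),
                      problem = character(0)))
  out <- do.call(rbind, fail)
  rownames(out) <- NULL
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a
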