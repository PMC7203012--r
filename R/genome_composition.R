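# -- genome composition: k-mer spectra and TE clustering ------------------------

#' Exact k-mer frequency spectrum of a sequence set
#'
#' Counts every k-mer occurrence over the given strand (no
#' reverse-complement canonicalization unless `canonical = TRUE`); k-mers
#' containing N are skipped.  The spectrum maps each frequency class x to the
#' number of distinct k-mers observed exactly x times.
#'
#' @param sequences Character vector (or `DNAStringSet`) over `A,C,G,T,N`.
#' @param k K-mer length (>= 1; must fit in at least one sequence).
#' @param canonical If TRUE, count k-mer and reverse complement as one unit.
#' @return List of class `kmer_spectrum`: `k`, `counts` (named integer
#'   vector: frequency class -> distinct k-mers), `total_kmers` (total
#'   occurrences), `distinct_kmers`.
#' @export
kmer_spectrum <- function(sequences, k, canonical = FALSE) {
  if (k < 1) stop("k must be >= 1")
  sequences <- toupper(as.character(sequences))
  if (length(sequences) && all(nchar(sequences) < k))
    stop("k is longer than every sequence")
  kmers <- character(0)
  for (s in sequences) {
    L <- nchar(s)
    if (L < k) next
    starts <- seq_len(L - k + 1)
    km <- substring(s, starts, starts + k - 1)
    km <- km[!grepl("N", km, fixed = TRUE)]
    kmers <- c(kmers, km)
  }
  if (canonical && length(kmers)) {
    rc <- as.character(Biostrings::reverseComplement(
      Biostrings::DNAStringSet(kmers)))
    kmers <- pmin(kmers, rc)
  }
  if (!length(kmers)) {
    return(structure(list(k = k, counts = integer(0), total_kmers = 0L,
                          distinct_kmers = 0L), class = "kmer_spectrum"))
  }
  freq <- table(kmers)
  spec <- table(as.integer(freq))
  counts <- setNames(as.integer(spec), names(spec))
  structure(list(k = k, counts = counts,
                 total_kmers = length(kmers),
                 distinct_kmers = length(freq)),
            class = "kmer_spectrum")
}

#' @export
print.kmer_spectrum <- function(x, ...) {
  cat("kmer_spectrum: k =", x$k, "|", x$distinct_kmers, "distinct /",
      x$total_kmers, "total\n")
  invisible(x)
}

#' Cumulative distinct-k-mer curves for labeled spectra
#'
#' Per label, the cumulative percentage of distinct k-mers whose frequency is
#' <= x; curves are monotone non-decreasing and end at 100.
#'
#' @param spectra Named list of `kmer_spectrum` objects (same k).
#' @return data.frame: `label`, `freq_class`, `cum_percent`.
#' @export
cumulative_curve <- function(spectra) {
  ks <- vapply(spectra, function(s) s$k, numeric(1))
  if (length(unique(ks)) != 1) stop("all spectra must share the same k")
  labs <- names(spectra)
  if (is.null(labs)) labs <- paste0("set", seq_along(spectra))
  rows <- lapply(seq_along(spectra), function(i) {
    s <- spectra[[i]]
    if (!length(s$counts))
      return(data.frame(label = labs[i], freq_class = integer(0),
                        cum_percent = numeric(0)))
    fc <- as.integer(names(s$counts))
    o <- order(fc)
    data.frame(label = labs[i], freq_class = fc[o],
               cum_percent = 100 * cumsum(s$counts[o]) / s$distinct_kmers,
               row.names = NULL)
  })
  do.call(rbind, rows)
}

# global pairwise identity = matches / alignment length; vectorized over `a`
global_identity <- function(a, b) {
  al <- Biostrings::pairwiseAlignment(Biostrings::DNAStringSet(a),
                                      Biostrings::DNAString(b),
                                      type = "global")
  Biostrings::nmatch(al) / Biostrings::width(Biostrings::alignedPattern(al))
}

#' Greedy identity clustering of TE sequences
#'
#' cd-hit-style contract at desk scale: sequences are processed longest
#' first; each joins the first existing cluster whose representative it
#' matches at global identity strictly greater than `threshold`, otherwise it
#' founds a new cluster.  Identity is matches / global alignment length.
#'
#' @param tes data.frame with columns `id`, `genome`, `seq` (>= 100 bp each).
#' @param threshold Identity threshold in (0, 1] (default 0.90).
#' @return List of class `te_cluster_set`: `clusters` (list of data.frames
#'   `id`, `genome`), `threshold`, `assignment` (data.frame `id`, `genome`,
#'   `cluster`).
#' @export
cluster_te_sequences <- function(tes, threshold = 0.90) {
  if (!nrow(tes)) stop("empty input")
  if (threshold <= 0 || threshold > 1) stop("threshold must be in (0, 1]")
  if (any(nchar(tes$seq) < 100)) stop("sequences must be >= 100 bp")
  ord <- order(-nchar(tes$seq), tes$id)   # longest first, id tiebreak
  tes <- tes[ord, , drop = FALSE]
  reps <- character(0)
  cluster <- integer(nrow(tes))
  for (i in seq_len(nrow(tes))) {
    hit <- 0L
    if (length(reps)) {
      ident <- global_identity(reps, tes$seq[i])
      m <- which(ident > threshold)          # first cluster wins
      if (length(m)) hit <- m[1]
    }
    if (hit == 0L) {
      reps <- c(reps, tes$seq[i])
      hit <- length(reps)
    }
    cluster[i] <- hit
  }
  assignment <- data.frame(id = tes$id, genome = tes$genome,
                           cluster = sprintf("cl%04d", cluster),
                           stringsAsFactors = FALSE)
  clusters <- lapply(split(assignment[, c("id", "genome")],
                           assignment$cluster), function(d)
                             d[order(d$id), , drop = FALSE])
  structure(list(clusters = clusters, threshold = threshold,
                 assignment = assignment), class = "te_cluster_set")
}

#' Classify TE clusters as genome-specific or shared
#'
#' A cluster whose members come from a single source genome is `specific`;
#' clusters spanning more than one genome are `shared`.
#'
#' @param clusters A `te_cluster_set`.
#' @return List: `table` (per cluster: `cluster`, `n_members`, `n_genomes`,
#'   `genomes`, `class`) and `summary` (per genome: specific / shared cluster
#'   counts).
#' @export
classify_cluster_sharing <- function(clusters) {
  a <- clusters$assignment
  if (any(is.na(a$genome) | !nzchar(a$genome)))
    stop("every member must carry a source-genome label")
  per <- lapply(split(a, a$cluster), function(d) {
    gs <- sort(unique(d$genome))
    data.frame(cluster = d$cluster[1], n_members = nrow(d),
               n_genomes = length(gs), genomes = paste(gs, collapse = ","),
               class = if (length(gs) == 1) "specific" else "shared",
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, per)
  rownames(tab) <- NULL
  genomes <- sort(unique(a$genome))
  summ <- do.call(rbind, lapply(genomes, function(g) {
    cl <- unique(a$cluster[a$genome == g])
    cls <- tab$class[match(cl, tab$cluster)]
    data.frame(genome = g, n_clusters = length(cl),
               specific = sum(cls == "specific"),
               shared = sum(cls == "shared"), stringsAsFactors = FALSE)
  }))
  list(table = tab, summary = summ)
}
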