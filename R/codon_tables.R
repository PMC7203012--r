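# -- genetic-code tables ------------------------------------------------------
#
# Shared by the codon simulator and the NG86 counter.  Codons are indexed
# 1..64 as 16*b1 + 4*b2 + b3 + 1 with A,C,G,T = 0,1,2,3.  Mutations to stop
# codons count as nonsynonymous in site counting (the classical NG86
# convention, which keeps N + S = 3 per codon); substitution pathways passing
# through a stop codon are excluded from pathway averaging.

.pr_cache <- new.env(parent = emptyenv())

NT <- c("A", "C", "G", "T")

codon_index <- function(b1, b2, b3) 16L * b1 + 4L * b2 + b3 + 1L

# all 64 codon strings in index order
all_codons <- function() {
  g <- expand.grid(b3 = 0:3, b2 = 0:3, b1 = 0:3)
  paste0(NT[g$b1 + 1], NT[g$b2 + 1], NT[g$b3 + 1])
}

build_codon_tables <- function() {
  codons <- all_codons()
  gc <- Biostrings::GENETIC_CODE
  aa <- unname(gc[codons])
  is_stop <- aa == "*"
  sense <- which(!is_stop)

  # per-codon digits
  dig <- cbind((seq_len(64) - 1) %/% 16,
               ((seq_len(64) - 1) %/% 4) %% 4,
               (seq_len(64) - 1) %% 4)

  # neighbor matrix: nb[codon, 9] = codon index after changing position p to
  # alternative base a (p slow, a fast); companion class matrix
  nb <- matrix(0L, 64, 9)
  for (ci in 1:64) {
    k <- 0
    for (p in 1:3) {
      for (a in setdiff(0:3, dig[ci, p])) {
        k <- k + 1
        d <- dig[ci, ]
        d[p] <- a
        nb[ci, k] <- codon_index(d[1], d[2], d[3])
      }
    }
  }
  nb_class <- matrix("", 64, 9)   # "syn", "nonsyn", "stop"
  for (ci in 1:64) {
    nb_class[ci, ] <- ifelse(is_stop[nb[ci, ]], "stop",
                             ifelse(aa[nb[ci, ]] == aa[ci], "syn", "nonsyn"))
  }

  # NG86 synonymous site fraction per codon (stops count as nonsynonymous)
  syn_sites <- rowSums(nb_class == "syn") / 3
  syn_sites[is_stop] <- NA_real_

  # pathway-averaged per-pair difference counts
  perms <- list(`1` = list(1L),
                `2` = list(c(1L, 2L), c(2L, 1L)),
                `3` = list(c(1L, 2L, 3L), c(1L, 3L, 2L), c(2L, 1L, 3L),
                           c(2L, 3L, 1L), c(3L, 1L, 2L), c(3L, 2L, 1L)))
  Sd <- matrix(NA_real_, 64, 64)
  Nd <- matrix(NA_real_, 64, 64)
  step_class <- function(x, y) if (aa[x] == aa[y]) "syn" else "nonsyn"
  for (i in sense) {
    for (j in sense) {
      if (j < i) next
      d <- which(dig[i, ] != dig[j, ])
      if (!length(d)) { Sd[i, j] <- Nd[i, j] <- 0; next }
      paths <- perms[[as.character(length(d))]]
      acc <- matrix(NA_real_, length(paths), 2)
      for (pi in seq_along(paths)) {
        cur <- dig[i, ]
        s <- n <- 0
        ok <- TRUE
        for (pos in d[paths[[pi]]]) {
          nxt <- cur
          nxt[pos] <- dig[j, pos]
          x <- codon_index(cur[1], cur[2], cur[3])
          y <- codon_index(nxt[1], nxt[2], nxt[3])
          if (is_stop[y]) { ok <- FALSE; break }
          if (step_class(x, y) == "syn") s <- s + 1 else n <- n + 1
          cur <- nxt
        }
        if (ok) acc[pi, ] <- c(s, n)
      }
      valid <- !is.na(acc[, 1])
      if (!any(valid)) {
        # all pathways blocked by stops: fall back to counting over all
        # pathways, treating the stop-crossing step as nonsynonymous
        for (pi in seq_along(paths)) {
          cur <- dig[i, ]
          s <- n <- 0
          for (pos in d[paths[[pi]]]) {
            nxt <- cur
            nxt[pos] <- dig[j, pos]
            x <- codon_index(cur[1], cur[2], cur[3])
            y <- codon_index(nxt[1], nxt[2], nxt[3])
            if (!is_stop[y] && step_class(x, y) == "syn") s <- s + 1 else n <- n + 1
            cur <- nxt
          }
          acc[pi, ] <- c(s, n)
        }
        valid <- rep(TRUE, length(paths))
      }
      Sd[i, j] <- Sd[j, i] <- mean(acc[valid, 1])
      Nd[i, j] <- Nd[j, i] <- mean(acc[valid, 2])
    }
  }
  list(codons = codons, aa = aa, is_stop = is_stop, sense = sense,
       digits = dig, neighbors = nb, neighbor_class = nb_class,
       syn_sites = syn_sites, Sd = Sd, Nd = Nd)
}

#' Genetic-code tables used by the codon simulator and NG86 counter
#'
#' Cached on first use.  `syn_sites` is the NG86 synonymous site fraction per
#' codon (mutations to stop codons counted as nonsynonymous); `Sd`/`Nd` are
#' 64 x 64 pathway-averaged synonymous/nonsynonymous difference counts with
#' stop-crossing pathways excluded.
#'
#' @return A list with elements `codons`, `aa`, `is_stop`, `sense`, `digits`,
#'   `neighbors`, `neighbor_class`, `syn_sites`, `Sd`, `Nd`.
#' @export
codon_tables <- function() {
  if (is.null(.pr_cache$codon_tables))
    .pr_cache$codon_tables <- build_codon_tables()
  .pr_cache$codon_tables
}

# nucleotide string <-> integer codes 0..3 (non-ACGT -> NA)
nt_to_int <- function(s) {
  x <- match(strsplit(toupper(s), "")[[1]], NT) - 1L
  x
}

int_to_nt <- function(x) paste(NT[x + 1L], collapse = "")

# integer nt vector -> codon indices (length L/3); NA where any nt is NA
codons_of <- function(x) {
  m <- matrix(x, nrow = 3)
  codon_index(m[1, ], m[2, ], m[3, ])
}
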