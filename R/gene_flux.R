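# -- gene gain/loss by weighted parsimony ---------------------------------------
#
# The likelihood mixture model used for genome-scale inference is replaced by
# loss-favoring weighted Sankoff parsimony (default loss:gain cost = 1:2)
# with deterministic tie-breaking; the root prior is anchored toward
# presence, since retained groups are present in both diploid progenitors by
# construction of the filter.

#' Build the diploid-anchored presence/absence matrix
#'
#' Keeps only ortholog groups present in BOTH diploids and absent in at least
#' one subgenome tip, and returns the binary matrix over the subgenome tips.
#'
#' @param ortholog_table data.frame with a `group` column and one 0/1 column
#'   per tip.
#' @param a_diploid,d_diploid Column names of the two diploids.
#' @param subgenome_tips Column names of the subgenome tips.
#' @return A `presence_matrix` over `subgenome_tips` (plus the two diploid
#'   columns, always 1 among retained groups).
#' @export
build_presence_matrix <- function(ortholog_table, a_diploid = "Ga",
                                  d_diploid = "Gr", subgenome_tips) {
  need <- c("group", a_diploid, d_diploid, subgenome_tips)
  miss <- setdiff(need, names(ortholog_table))
  if (length(miss)) stop("ortholog table lacks column(s): ",
                         paste(miss, collapse = ", "))
  m <- as.matrix(ortholog_table[, c(a_diploid, d_diploid, subgenome_tips)])
  if (!all(m %in% c(0, 1))) stop("ortholog table entries must be 0/1")
  keep <- m[, a_diploid] == 1 & m[, d_diploid] == 1 &
    rowSums(m[, subgenome_tips, drop = FALSE] == 0) >= 1
  mat <- m[keep, , drop = FALSE]
  storage.mode(mat) <- "integer"
  rownames(mat) <- ortholog_table$group[keep]
  structure(list(matrix = mat, tips = colnames(mat),
                 groups = rownames(mat)),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence_matrix:", length(x$groups), "groups x", length(x$tips), "tips\n")
  invisible(x)
}

# postorder node list for an ape phylo: list(children per node), tips first
phylo_postorder <- function(tree) {
  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  children <- vector("list", nn)
  for (i in seq_len(nrow(tree$edge)))
    children[[tree$edge[i, 1]]] <- c(children[[tree$edge[i, 1]]], tree$edge[i, 2])
  po <- ape::reorder.phylo(tree, "postorder")$edge
  order <- unique(c(po[, 2], po[nrow(po), 1]))   # children before parents
  list(children = children, order = order, n_tip = nt,
       root = nt + 1L, labels = tree$tip.label)
}

#' Per-branch gene gains and losses by weighted Sankoff parsimony
#'
#' For each group, the minimum-cost ancestral presence labeling is found by
#' two-state Sankoff dynamic programming with branch costs
#' `gain_weight` (0 -> 1) and `loss_weight` (1 -> 0); the root additionally
#' pays `gain_weight` for state 0 (absence), anchoring the root toward
#' presence.  Ties are broken by preferring the labeling with fewer gains
#' (no-event > loss > gain) in a deterministic preorder traversal.
#'
#' @param presence A `presence_matrix`.
#' @param tree [ape::phylo] whose tip labels cover the matrix' subgenome
#'   tips (diploid columns, if present in the matrix, are ignored here; they
#'   anchor the root prior instead).
#' @param loss_weight,gain_weight Positive costs with
#'   `loss_weight <= gain_weight` (default 1 and 2).
#' @return List of class `flux_map`: `branches` (data.frame `branch` (child
#'   node label), `gains`, `losses`), `events` (per group placements),
#'   `total_cost`.
#' @export
parsimony_flux <- function(presence, tree, loss_weight = 1, gain_weight = 2) {
  if (loss_weight <= 0 || gain_weight <= 0 || loss_weight > gain_weight)
    stop("weights must satisfy 0 < loss_weight <= gain_weight")
  tips <- intersect(presence$tips, tree$tip.label)
  if (!setequal(tree$tip.label, tips))
    stop("tree tips must match the matrix' subgenome tips")
  mat <- presence$matrix[, tree$tip.label, drop = FALSE]

  nt <- length(tree$tip.label)
  nn <- nt + tree$Nnode
  topo <- phylo_postorder(tree)
  node_lab <- c(tree$tip.label,
                if (!is.null(tree$node.label) && all(nzchar(tree$node.label)))
                  tree$node.label else paste0("n", seq_len(tree$Nnode)))
  parent <- rep(NA_integer_, nn)
  parent[tree$edge[, 2]] <- tree$edge[, 1]

  # transition cost from parent state s to child state t
  trans <- matrix(c(0, gain_weight, loss_weight, 0), 2, 2, byrow = TRUE)

  branch_gain <- setNames(numeric(nn), node_lab)
  branch_loss <- setNames(numeric(nn), node_lab)
  events <- list()
  total_cost <- 0

  for (g in seq_len(nrow(mat))) {
    cost <- matrix(Inf, nn, 2)              # cost[v, s+1]
    for (i in seq_len(nt)) {
      st <- mat[g, i]
      cost[i, ] <- c(if (st == 0) 0 else Inf, if (st == 1) 0 else Inf)
    }
    for (v in topo$order) {
      kids <- topo$children[[v]]
      if (is.null(kids)) next
      for (s in 0:1) {
        tot <- 0
        for (ch in kids)
          tot <- tot + min(trans[s + 1, 1] + cost[ch, 1],
                           trans[s + 1, 2] + cost[ch, 2])
        cost[v, s + 1] <- tot
      }
    }
    root <- topo$root
    root_cost <- cost[root, ] + c(gain_weight, 0)   # presence-anchored prior
    total_cost <- total_cost + min(root_cost)
    state <- integer(nn)
    state[root] <- if (root_cost[2] <= root_cost[1]) 1L else 0L
    # preorder backtrace; tie preference: no event > loss > gain
    pre <- rev(topo$order)
    for (v in pre) {
      kids <- topo$children[[v]]
      if (is.null(kids)) next
      s <- state[v]
      for (ch in kids) {
        c_same <- trans[s + 1, s + 1] + cost[ch, s + 1]
        c_flip <- trans[s + 1, 2 - s] + cost[ch, 2 - s]
        # exact ties keep the parent state (no event beats loss beats gain)
        state[ch] <- if (c_flip < c_same) 1L - s else s
        if (state[ch] != s) {
          if (s == 1L) {
            branch_loss[node_lab[ch]] <- branch_loss[node_lab[ch]] + 1
            events[[length(events) + 1]] <-
              data.frame(group = rownames(mat)[g], branch = node_lab[ch],
                         type = "loss")
          } else {
            branch_gain[node_lab[ch]] <- branch_gain[node_lab[ch]] + 1
            events[[length(events) + 1]] <-
              data.frame(group = rownames(mat)[g], branch = node_lab[ch],
                         type = "gain")
          }
        }
      }
    }
  }
  events <- if (length(events)) do.call(rbind, events) else
    data.frame(group = character(0), branch = character(0), type = character(0))
  branches <- data.frame(branch = node_lab, gains = branch_gain,
                         losses = branch_loss, row.names = NULL,
                         stringsAsFactors = FALSE)[!is.na(parent), ]
  structure(list(branches = branches, events = events,
                 total_cost = total_cost,
                 loss_weight = loss_weight, gain_weight = gain_weight),
            class = "flux_map")
}

#' @export
print.flux_map <- function(x, ...) {
  cat("flux_map:", sum(x$branches$losses), "losses,",
      sum(x$branches$gains), "gains; total cost", x$total_cost, "\n")
  invisible(x)
}
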