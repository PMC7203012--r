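#' @importFrom stats median pchisq pnorm rbinom rgamma rmultinom rpois runif
#'   rbeta anova lm cor setNames quantile sd rexp complete.cases
#' @importFrom utils head tail write.table read.table packageVersion
NULL

# -- species history ----------------------------------------------------------
#
# A dated, rooted species/subgenome tree.  Internally a node table rather than
# an ape "phylo", because the simulator needs node ages in years and
# per-branch rate multipliers, neither of which phylo carries.  Conversion to
# phylo (branch lengths in years) is provided for interop and Newick I/O.

#' Default split times (years) for the allotetraploid cotton history
#'
#' Node ages used by [make_history()] when no `split_times` are supplied:
#' outgroup (Theobroma-like) at 58.5 Ma, A/D diploid divergence at 5.0 Ma,
#' polyploid/diploid divergence at 1.5 Ma, Gm versus the other four
#' tetraploids at 0.63 Ma, the (Gh,Gt)/(Gb,Gd) split at 0.45 Ma, Gh-Gt at
#' 0.30 Ma and Gb-Gd at 0.20 Ma.
#'
#' @return Named list of split times in years.
#' @export
cotton_split_times <- function() {
  list(
    outgroup         = 58.5e6,
    diploids         = 5.0e6,
    polyploid_origin = 1.5e6,
    gm_split         = 0.63e6,
    ghgt_gbgd_split  = 0.45e6,
    gh_gt_split      = 0.30e6,
    gb_gd_split      = 0.20e6
  )
}

#' Build a dated allopolyploid species history
#'
#' Constructs the rooted, dated tree over an outgroup, the two diploid
#' progenitor proxies (`Ga`, the A-genome diploid; `Gr`, the D-genome
#' diploid) and the A and D subgenome tips of the five allotetraploids
#' (`Gh`, `Gb`, `Gt`, `Gm`, `Gd`).  Subgenome tips attach inside their
#' progenitor's clade (amphidiploid structure): `Gh_At` etc. are sister to
#' `Ga`, `Gh_Dt` etc. to `Gr`.  Expected branch lengths in substitutions per
#' site are `clock_rate * years * multiplier`.
#'
#' @param split_times Named list of node ages in years; see
#'   [cotton_split_times()] for the recognized names and defaults.  Partial
#'   lists override the defaults.
#' @param clock_rate Synonymous substitution rate per site per year
#'   (default `3.48e-9`, the cotton rate).
#' @param multipliers Named numeric vector of per-branch rate multipliers,
#'   named by the child node of each branch (e.g. `c(Gh_At = 1.5)`).
#'   Unnamed branches get multiplier 1.
#' @return An object of class `species_history`.
#' @export
make_history <- function(split_times = NULL, clock_rate = 3.48e-9,
                         multipliers = NULL) {
  st <- cotton_split_times()
  if (!is.null(split_times)) {
    bad <- setdiff(names(split_times), names(st))
    if (length(bad)) stop("unknown split time name(s): ", paste(bad, collapse = ", "))
    st[names(split_times)] <- split_times
  }
  if (!is.numeric(clock_rate) || clock_rate <= 0)
    stop("clock_rate must be a positive number")
  times <- unlist(st)
  if (any(!is.finite(times)) || any(times < 0))
    stop("split times must be finite and non-negative")

  node <- function(id, parent, time) data.frame(id = id, parent = parent,
                                                time = time, stringsAsFactors = FALSE)
  poly_clade <- function(sub, crown, n1, n2, n3) {
    rbind(
      node(crown, if (sub == "At") "cladeA" else "cladeD", st$gm_split),
      node(paste0("Gm_", sub), crown, 0),
      node(n1, crown, st$ghgt_gbgd_split),
      node(n2, n1, st$gh_gt_split),
      node(paste0("Gh_", sub), n2, 0),
      node(paste0("Gt_", sub), n2, 0),
      node(n3, n1, st$gb_gd_split),
      node(paste0("Gb_", sub), n3, 0),
      node(paste0("Gd_", sub), n3, 0)
    )
  }
  nodes <- rbind(
    node("root", NA_character_, st$outgroup),
    node("outgroup", "root", 0),
    node("cotton", "root", st$diploids),
    node("cladeA", "cotton", st$polyploid_origin),
    node("Ga", "cladeA", 0),
    poly_clade("At", "polyA", "polyA1", "polyA2", "polyA3"),
    node("cladeD", "cotton", st$polyploid_origin),
    node("Gr", "cladeD", 0),
    poly_clade("Dt", "polyD", "polyD1", "polyD2", "polyD3")
  )
  nodes$multiplier <- 1
  if (!is.null(multipliers)) {
    if (is.null(names(multipliers)) || any(names(multipliers) == ""))
      stop("multipliers must be a named vector (names = child node of branch)")
    bad <- setdiff(names(multipliers), nodes$id)
    if (length(bad)) stop("multiplier refers to unknown node(s): ",
                          paste(bad, collapse = ", "))
    if (any(!is.finite(multipliers)) || any(multipliers < 0))
      stop("rate multipliers must be finite and >= 0")
    nodes$multiplier[match(names(multipliers), nodes$id)] <- multipliers
  }
  new_history(nodes, clock_rate)
}

# internal constructor + validator shared by make_history and prune/read paths
new_history <- function(nodes, clock_rate) {
  stopifnot(all(c("id", "parent", "time", "multiplier") %in% names(nodes)))
  if (anyDuplicated(nodes$id)) stop("duplicate node ids")
  root <- nodes$id[is.na(nodes$parent)]
  if (length(root) != 1) stop("history must have exactly one root")
  if (any(nodes$time < 0)) stop("negative node time")
  pidx <- match(nodes$parent, nodes$id)
  if (any(is.na(pidx) & !is.na(nodes$parent))) stop("parent not in node table")
  ok <- is.na(nodes$parent) | nodes$time <= nodes$time[pidx]
  if (!all(ok))
    stop("non-ultrametric time assignment: node(s) older than parent: ",
         paste(nodes$id[!ok], collapse = ", "))
  is_tip <- !(nodes$id %in% nodes$parent)
  tips <- nodes$id[is_tip]
  parse_tip <- function(lab) {
    if (grepl("_(At|Dt)$", lab)) {
      c(taxon = sub("_(At|Dt)$", "", lab), subgenome = sub("^.*_", "", lab))
    } else if (lab == "Ga") c(taxon = "Ga", subgenome = "A")
    else if (lab == "Gr") c(taxon = "Gr", subgenome = "D")
    else c(taxon = lab, subgenome = "out")
  }
  meta <- t(vapply(tips, parse_tip, character(2)))
  structure(list(
    nodes = nodes,
    clock_rate = clock_rate,
    tips = data.frame(tip = tips, taxon = meta[, "taxon"],
                      subgenome = meta[, "subgenome"],
                      row.names = NULL, stringsAsFactors = FALSE)
  ), class = "species_history")
}

#' @export
print.species_history <- function(x, ...) {
  cat("species_history:", nrow(x$tips), "tips,",
      nrow(x$nodes) - nrow(x$tips), "internal nodes\n")
  cat("  clock rate:", format(x$clock_rate, digits = 4), "subs/site/year\n")
  cat("  root age:", format(max(x$nodes$time), big.mark = ","), "years\n")
  invisible(x)
}

#' Expected branch lengths in substitutions per site
#'
#' One entry per branch, named by the branch's child node; equals
#' `clock_rate * (age(parent) - age(child)) * multiplier`.
#'
#' @param history A `species_history`.
#' @return Named numeric vector (root omitted).
#' @export
branch_expected_subs <- function(history) {
  n <- history$nodes
  pidx <- match(n$parent, n$id)
  keep <- !is.na(n$parent)
  setNames(history$clock_rate * (n$time[pidx][keep] - n$time[keep]) *
             n$multiplier[keep], n$id[keep])
}

# path from a node up to the root, as a vector of node ids (inclusive)
path_to_root <- function(history, tip) {
  n <- history$nodes
  cur <- tip
  out <- character(0)
  while (!is.na(cur)) {
    out <- c(out, cur)
    cur <- n$parent[match(cur, n$id)]
  }
  out
}

#' Expected pairwise divergence between two tips (substitutions/site)
#'
#' Sum of expected branch lengths along the path connecting the two tips.
#'
#' @param history A `species_history`.
#' @param tip1,tip2 Tip labels.
#' @return Expected number of substitutions per site separating the tips.
#' @export
expected_pair_divergence <- function(history, tip1, tip2) {
  b <- branch_expected_subs(history)
  p1 <- path_to_root(history, tip1)
  p2 <- path_to_root(history, tip2)
  mrca <- p1[p1 %in% p2][1]
  on_path <- c(p1[seq_len(match(mrca, p1) - 1)], p2[seq_len(match(mrca, p2) - 1)])
  sum(b[on_path])
}

#' Restrict a history to a subset of tips
#'
#' Drops all other tips and splices out the resulting unary internal nodes;
#' multipliers of spliced branches are combined as time-weighted means so
#' expected substitutions per site along every retained path are preserved.
#'
#' @param history A `species_history`.
#' @param tips Character vector of tip labels to keep (>= 2).
#' @return A `species_history` over `tips`.
#' @export
prune_history <- function(history, tips) {
  n <- history$nodes
  if (!all(tips %in% history$tips$tip))
    stop("unknown tip(s): ", paste(setdiff(tips, history$tips$tip), collapse = ", "))
  if (length(tips) < 2) stop("need at least two tips")
  keep <- unique(unlist(lapply(tips, path_to_root, history = history)))
  n <- n[n$id %in% keep, ]
  repeat {
    is_tip_now <- !(n$id %in% n$parent)
    drop_tips <- n$id[is_tip_now & !(n$id %in% tips)]
    child_count <- table(factor(n$parent, levels = n$id))
    root_id <- n$id[is.na(n$parent)]
    unary <- names(child_count)[child_count == 1]
    if (!length(drop_tips) && !length(unary)) break
    if (length(drop_tips)) {
      n <- n[!(n$id %in% drop_tips), ]
      next
    }
    u <- unary[1]
    ch <- n$id[!is.na(n$parent) & n$parent == u]
    ui <- match(u, n$id); ci <- match(ch, n$id)
    if (u == root_id) {
      # root with single child: new root is the child
      n$parent[ci] <- NA_character_
      n <- n[-ui, ]
    } else {
      du <- n$time[match(n$parent[ui], n$id)] - n$time[ui]
      dc <- n$time[ui] - n$time[ci]
      tot <- du + dc
      n$multiplier[ci] <- if (tot > 0)
        (du * n$multiplier[ui] + dc * n$multiplier[ci]) / tot else 1
      n$parent[ci] <- n$parent[ui]
      n <- n[-match(u, n$id), ]
    }
  }
  new_history(n, history$clock_rate)
}

#' Convert a history to an ape phylogeny (branch lengths in years)
#'
#' @param history A `species_history`.
#' @return An [ape::phylo] object with node labels and edge lengths in years.
#' @export
history_to_phylo <- function(history) {
  ape::read.tree(text = history_newick(history))
}

# newick string with branch lengths in years and internal node labels
history_newick <- function(history) {
  n <- history$nodes
  children <- split(n$id[!is.na(n$parent)], n$parent[!is.na(n$parent)])
  rec <- function(id) {
    kids <- children[[id]]
    ii <- match(id, n$id)
    bl <- if (is.na(n$parent[ii])) "" else
      paste0(":", format(n$time[match(n$parent[ii], n$id)] - n$time[ii],
                         scientific = FALSE, trim = TRUE))
    if (is.null(kids)) return(paste0(id, bl))
    paste0("(", paste(vapply(kids, rec, character(1)), collapse = ","), ")", id, bl)
  }
  paste0(rec(n$id[is.na(n$parent)]), ";")
}

#' Write / read a history as Newick (branch lengths in years)
#'
#' The clock rate is stored as a bracketed annotation comment on a separate
#' line (`[&clock_rate=...]`); rate multipliers are run configuration and are
#' not serialized.
#'
#' @param history A `species_history`.
#' @param path Output file.
#' @return `write_history_newick` returns `path` invisibly;
#'   `read_history_newick` returns a `species_history`.
#' @export
write_history_newick <- function(history, path) {
  writeLines(c(history_newick(history),
               sprintf("[&clock_rate=%.10e]", history$clock_rate)), path)
  invisible(path)
}

#' @rdname write_history_newick
#' @export
read_history_newick <- function(path) {
  txt <- paste(readLines(path, warn = FALSE), collapse = "\n")
  rate <- 3.48e-9
  m <- regmatches(txt, regexec("\\[&clock_rate=([0-9.eE+-]+)\\]", txt))[[1]]
  if (length(m) == 2) rate <- as.numeric(m[2])
  txt <- gsub("\\[[^]]*\\]", "", txt)
  phy <- ape::read.tree(text = txt)
  phylo_to_history(phy, clock_rate = rate)
}

# rebuild the node table from a phylo whose edge lengths are years
phylo_to_history <- function(phy, clock_rate = 3.48e-9) {
  ntip <- length(phy$tip.label)
  nnode <- phy$Nnode
  labs <- c(phy$tip.label,
            if (!is.null(phy$node.label) && all(nzchar(phy$node.label)))
              phy$node.label else paste0("n", seq_len(nnode)))
  depth <- numeric(ntip + nnode)
  ord <- ape::reorder.phylo(phy, "postorder")$edge
  for (i in rev(seq_len(nrow(ord)))) {   # preorder over edges
    e <- match(paste(ord[i, 1], ord[i, 2]),
               paste(phy$edge[, 1], phy$edge[, 2]))
    depth[ord[i, 2]] <- depth[ord[i, 1]] + phy$edge.length[e]
  }
  age <- max(depth) - depth
  parent <- rep(NA_character_, ntip + nnode)
  parent[phy$edge[, 2]] <- labs[phy$edge[, 1]]
  nodes <- data.frame(id = labs, parent = parent, time = age,
                      multiplier = 1, stringsAsFactors = FALSE)
  new_history(nodes, clock_rate)
}

#' Phylogeny over the ten subgenome tips
#'
#' Convenience accessor used by the gene gain/loss stage: the history pruned
#' to the five At and five Dt tips, as an ape phylogeny.
#'
#' @param history A `species_history` (cotton-shaped).
#' @return An [ape::phylo] with 10 tips.
#' @export
subgenome_tree <- function(history) {
  tips <- history$tips$tip[history$tips$subgenome %in% c("At", "Dt")]
  history_to_phylo(prune_history(history, tips))
}
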