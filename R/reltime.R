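#' Relative divergence times and lineage rates
#'
#' A RelTime-style relative dating of a rooted tree with branch lengths in
#' substitutions/site. For each node the tip-count-weighted mean tip-path
#' length `L(v)` is computed bottom-up; relative node times then follow the
#' recursion `T(child) = T(parent) * L(child) / (b + L(child))`, which makes
#' every sibling lineage span the same elapsed time from the shared parent
#' to the present (rate differences between sibling lineages are absorbed
#' into relative rates instead of time). Tips sit at time 0 and the ingroup
#' root is normalized to time 1. The relative rate of each branch is its
#' length divided by its elapsed time, normalized to mean 1 over ingroup
#' branches; zero-elapsed branches get rate 1 by convention. On a
#' strictly clock-like (ultrametric) ingroup all rates are 1 and times are
#' proportional to node heights. Both times and rates are invariant to a
#' global rescaling of branch lengths.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param outgroup_ids Optional character vector of outgroup leaf labels;
#'   the tree is rooted on the outgroup if not already, and the outgroup is
#'   excluded from rate estimation and time normalization. A warning is
#'   given if the outgroup is not monophyletic.
#' @return A `reltime_result`: list with `times` (data frame: node label,
#'   relative_time) and `branches` (data frame: child label, parent label,
#'   branch_length, elapsed, relative_rate), plus `tree` (ingroup subtree,
#'   labeled).
#' @export
relative_rates <- function(tree, outgroup_ids = NULL) {
  validate_tree(tree)
  if (!is.null(outgroup_ids) && length(outgroup_ids)) {
    missing <- setdiff(outgroup_ids, tree$tip.label)
    if (length(missing))
      stop("outgroup leaf label(s) not in tree: ",
           paste(missing, collapse = ", "))
    root_on <- outgroup_ids
    if (!ape::is.monophyletic(tree, outgroup_ids)) {
      warning("outgroup is not monophyletic; rooting on its first member")
      root_on <- outgroup_ids[1]
    }
    tree <- ape::root(tree, outgroup = root_on, resolve.root = TRUE)
    ingroup <- setdiff(tree$tip.label, outgroup_ids)
    tree <- ape::keep.tip(tree, ingroup)
  }
  if (!ape::is.rooted(tree))
    stop("tree must be rooted (or provide outgroup_ids)")
  tree <- label_nodes(tree, keep = TRUE)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  blen <- numeric(nnode)                 # branch above each node
  blen[po$edge[, 2]] <- po$edge.length
  ntips_below <- rep(1, nnode)
  L <- numeric(nnode)                    # mean tip-path length below node
  for (v in unique(po$edge[, 1])) {
    kids <- po$edge[po$edge[, 1] == v, 2]
    ntips_below[v] <- sum(ntips_below[kids])
    L[v] <- sum(ntips_below[kids] * (blen[kids] + L[kids])) / ntips_below[v]
  }
  root <- ntip + 1L
  Tt <- numeric(nnode)
  Tt[root] <- 1
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; c <- edges[e, 2]
    h <- blen[c] + L[c]
    Tt[c] <- if (h > 0) Tt[u] * L[c] / h else Tt[u]
  }
  elapsed <- numeric(nnode)
  rate <- rep(NA_real_, nnode)
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; c <- edges[e, 2]
    elapsed[c] <- Tt[u] - Tt[c]
    rate[c] <- if (elapsed[c] > 0) blen[c] / elapsed[c] else 1
  }
  child_nodes <- po$edge[, 2]
  rate[child_nodes] <- rate[child_nodes] / mean(rate[child_nodes])
  labs <- node_labels(tree)
  times <- data.frame(node = labs, relative_time = Tt,
                      stringsAsFactors = FALSE)
  parent_of <- integer(nnode)
  parent_of[po$edge[, 2]] <- po$edge[, 1]
  branches <- data.frame(child = labs[child_nodes],
                         parent = labs[parent_of[child_nodes]],
                         branch_length = blen[child_nodes],
                         elapsed = elapsed[child_nodes],
                         relative_rate = rate[child_nodes],
                         stringsAsFactors = FALSE)
  structure(list(times = times, branches = branches, tree = tree),
            class = "reltime_result")
}

#' @export
print.reltime_result <- function(x, ...) {
  cat(sprintf("reltime_result: %d nodes, %d branches (ingroup root at 1)\n",
              nrow(x$times), nrow(x$branches)))
  invisible(x)
}

#' Write a relative-time table
#'
#' @param rt A `reltime_result`.
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_reltime <- function(rt, path) {
  df <- merge(rt$branches, rt$times, by.x = "child", by.y = "node",
              sort = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
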