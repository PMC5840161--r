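#' Read and write Newick trees
#'
#' Wrappers around [ape::read.tree()] / [ape::write.tree()] with the
#' validation this pipeline relies on: branch lengths must be present and
#' non-negative, leaf labels unique, and internal node labels (the `N#`
#' ancestor labels) survive a round trip.
#'
#' @param path File path.
#' @return `read_newick()`: an [ape::phylo] tree.
#' @export
read_newick <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  tr <- tryCatch(ape::read.tree(path),
                 error = function(e) stop("invalid Newick in ", path, ": ",
                                          conditionMessage(e)))
  if (is.null(tr)) stop("invalid Newick in ", path)
  validate_tree(tr)
  tr
}

#' @rdname read_newick
#' @param tree An [ape::phylo] tree.
#' @return `write_newick()`: the path, invisibly.
#' @export
write_newick <- function(tree, path) {
  validate_tree(tree)
  ape::write.tree(tree, file = path, digits = 12)
  invisible(path)
}

validate_tree <- function(tree) {
  stopifnot(inherits(tree, "phylo"))
  if (is.null(tree$edge.length))
    stop("tree has no branch lengths")
  if (any(tree$edge.length < 0))
    stop("negative branch length(s) in tree")
  if (anyDuplicated(tree$tip.label))
    stop("duplicate leaf labels: ",
         paste(unique(tree$tip.label[duplicated(tree$tip.label)]),
               collapse = ", "))
  invisible(tree)
}

#' Label internal nodes deterministically
#'
#' Assigns internal node labels `N<k>` by post-order traversal so that two
#' runs on the same topology give identical labels. Existing labels are
#' overwritten unless `keep = TRUE` and labels are already present.
#'
#' @param tree An [ape::phylo] tree.
#' @param prefix Label prefix (default `"N"`).
#' @param keep If `TRUE`, keep existing non-empty labels.
#' @return The tree with `node.label` set.
#' @export
label_nodes <- function(tree, prefix = "N", keep = FALSE) {
  n_int <- tree$Nnode
  if (keep && !is.null(tree$node.label) && all(nzchar(tree$node.label)))
    return(tree)
  po <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  internal_order <- unique(po$edge[, 1])      # parents in postorder
  lab <- character(n_int)
  lab[internal_order - ntip] <- paste0(prefix, seq_along(internal_order))
  tree$node.label <- lab
  tree
}

# node number -> display label (tips use tip.label, internals node.label)
node_labels <- function(tree) {
  ntip <- length(tree$tip.label)
  nl <- tree$node.label
  if (is.null(nl) || !all(nzchar(nl)))
    nl <- paste0("node", ntip + seq_len(tree$Nnode))
  c(tree$tip.label, nl)
}

#' Find an internal node by its set of descendant leaves
#'
#' Internal node labels produced by different programs are arbitrary; the
#' stable identity of an ancestor is the set of leaves it subtends. Given a
#' leaf set, returns the matching node number (or `NA` if no node subtends
#' exactly that set).
#'
#' @param tree An [ape::phylo] tree.
#' @param leaves Character vector of leaf labels.
#' @return Integer node number, or `NA_integer_`.
#' @export
match_node_by_leafset <- function(tree, leaves) {
  ntip <- length(tree$tip.label)
  target <- sort(unique(leaves))
  for (v in (ntip + 1L):(ntip + tree$Nnode)) {
    tips <- tree$tip.label[descendant_tips(tree, v)]
    if (identical(sort(tips), target)) return(v)
  }
  NA_integer_
}

# indices of tips below node v
descendant_tips <- function(tree, v) {
  ntip <- length(tree$tip.label)
  if (v <= ntip) return(v)
  kids <- tree$edge[tree$edge[, 1] == v, 2]
  unlist(lapply(kids, descendant_tips, tree = tree))
}
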