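## Felsenstein pruning machinery. Sites are compressed to unique column
## patterns; partial likelihood vectors are (nstates x npatterns) matrices
## so each peel step is one dense matrix product. Per-node scaling keeps
## partials in range on deep trees (log accumulators per pattern).

# Compress an aligned seq_set restricted to `ids` into patterns.
# Gaps and unknowns ('X' for protein, 'N' for DNA) are missing data:
# their tip partial is a vector of ones.
compress_patterns <- function(msa, ids, model) {
  m <- seq_matrix(msa)
  missing <- setdiff(ids, rownames(m))
  if (length(missing))
    stop("leaf name(s) missing from alignment: ",
         paste(missing, collapse = ", "))
  m <- m[ids, , drop = FALSE]
  key <- apply(m, 2, paste, collapse = "\r")
  pat <- match(key, unique(key))
  upat <- which(!duplicated(key))
  weights <- as.vector(table(factor(pat, levels = seq_along(upat))))
  nstates <- length(model$states)
  tip_partials <- lapply(ids, function(id) {
    chars <- m[id, upat]
    idx <- match(chars, model$states)
    tp <- matrix(0, nstates, length(upat))
    known <- !is.na(idx)
    tp[cbind(idx[known], which(known))] <- 1
    tp[, !known] <- 1
    tp
  })
  names(tip_partials) <- ids
  list(tip_partials = tip_partials, weights = weights,
       site_to_pattern = pat, npat = length(upat))
}

# Post-order peel. Returns per-node partials (tips included), the per-node
# transition matrices used, and the accumulated log-scaling per pattern.
peel <- function(tree, cp, model, rate = 1) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  po <- ape::reorder.phylo(tree, "postorder")
  nstates <- length(model$states)
  partials <- vector("list", nnode)
  for (i in seq_len(ntip)) partials[[i]] <- cp$tip_partials[[tree$tip.label[i]]]
  logscale <- numeric(cp$npat)
  Pmats <- vector("list", nnode)  # P along branch above each node
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    Pmats[[child]] <- transition_matrix(model, po$edge.length[e], rate)
  }
  parents <- unique(po$edge[, 1])  # postorder guarantees children first
  for (v in parents) {
    kids <- po$edge[po$edge[, 1] == v, 2]
    acc <- matrix(1, nstates, cp$npat)
    for (c in kids) acc <- acc * (Pmats[[c]] %*% partials[[c]])
    sc <- apply(acc, 2, max)
    sc[sc == 0] <- 1
    partials[[v]] <- sweep(acc, 2, sc, "/")
    logscale <- logscale + log(sc)
  }
  list(partials = partials, Pmats = Pmats, logscale = logscale,
       root = ntip + 1L)
}

# per-pattern log-likelihood for one rate category
pattern_loglik_onerate <- function(tree, cp, model, rate) {
  pl <- peel(tree, cp, model, rate)
  lroot <- as.vector(model$frequencies %*% pl$partials[[pl$root]])
  log(lroot) + pl$logscale
}

# per-pattern log-likelihood, mixing over gamma categories
pattern_loglik <- function(tree, cp, model) {
  k <- length(model$rates)
  if (k == 1L)
    return(pattern_loglik_onerate(tree, cp, model, model$rates[1]))
  ll <- vapply(seq_len(k), function(i)
    pattern_loglik_onerate(tree, cp, model, model$rates[i]),
    numeric(cp$npat))
  # log-sum-exp across categories with equal weights
  mx <- apply(ll, 1, max)
  mx + log(rowMeans(exp(ll - mx)))
}

#' Tree log-likelihood by Felsenstein pruning
#'
#' Sums per-site log-likelihoods over the alignment under a reversible
#' substitution model, with gaps and unknown residues treated as missing
#' data. For reversible models the value is invariant to root placement.
#' With discrete-gamma rate variation the site likelihood is the
#' equal-weight mixture over categories.
#'
#' @param tree An [ape::phylo] tree with branch lengths; its leaf labels
#'   must all appear in `msa`.
#' @param msa Aligned [seq_set()].
#' @param model A [subst_model()] over the alphabet of `msa`.
#' @return Total log-likelihood (a single number).
#' @export
log_likelihood <- function(tree, msa, model) {
  validate_tree(tree)
  stopifnot(inherits(msa, "seq_set"), msa$aligned)
  cp <- compress_patterns(msa, tree$tip.label, model)
  sum(cp$weights * pattern_loglik(tree, cp, model))
}
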