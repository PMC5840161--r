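#' Pairwise evolutionary distance between two aligned sequences
#'
#' Under `poisson_equal` the distance has the closed form
#' `d = -(19/20) log(1 - (20/19) p)` with `p` the observed mismatch
#' proportion over co-ungapped columns (the amino-acid analogue of the
#' Jukes-Cantor correction). Under an empirical model the distance is the
#' maximum-likelihood branch length of the two-sequence tree, found by 1-D
#' optimization. Saturated pairs (`p >= 19/20`, or beyond `d_max` for ML)
#' return `d_max` with a warning.
#'
#' @param seq_a,seq_b Aligned sequences (equal length, character scalars).
#' @param model A [subst_model()].
#' @param d_max Saturation cap (default 10).
#' @return Distance in substitutions/site.
#' @export
#' @examples
#' m <- subst_model("poisson_equal")
#' pairwise_distance("AAAA", "AAAA", m)  # 0
pairwise_distance <- function(seq_a, seq_b, model, d_max = 10) {
  a <- strsplit(toupper(seq_a), "")[[1]]
  b <- strsplit(toupper(seq_b), "")[[1]]
  if (length(a) != length(b)) stop("sequences differ in aligned length")
  keep <- a %in% model$states & b %in% model$states
  if (!any(keep)) stop("no co-ungapped columns between the two sequences")
  a <- a[keep]; b <- b[keep]
  n <- length(model$states)
  if (model$kind %in% c("poisson_equal", "nucleotide")) {
    p <- mean(a != b)
    crit <- (n - 1) / n
    if (p >= crit) {
      warning("mismatch proportion at or beyond saturation; returning d_max")
      return(d_max)
    }
    return(-crit * log(1 - p / crit))
  }
  # empirical model: ML distance on a two-sequence likelihood
  ia <- match(a, model$states); ib <- match(b, model$states)
  pairs <- table(factor(ia, 1:n), factor(ib, 1:n))
  negll <- function(t) {
    P <- transition_matrix(model, t)
    -sum(pairs * log(pmax(model$frequencies * P, 1e-300)))
  }
  opt <- optimize(negll, interval = c(1e-9, d_max), tol = 1e-9)
  if (opt$minimum > d_max - 1e-3 && negll(d_max) <= opt$objective) {
    warning("ML distance at saturation cap; returning d_max")
    return(d_max)
  }
  opt$minimum
}

#' All pairwise distances for an aligned sequence set
#'
#' @param msa Aligned [seq_set()].
#' @param model A [subst_model()].
#' @param d_max Saturation cap passed to [pairwise_distance()].
#' @return Symmetric distance matrix with sequence ids as dimnames.
#' @export
distance_matrix <- function(msa, model, d_max = 10) {
  stopifnot(inherits(msa, "seq_set"), msa$aligned)
  n <- nseq(msa)
  D <- matrix(0, n, n, dimnames = list(msa$ids, msa$ids))
  for (i in seq_len(n - 1)) for (j in (i + 1):n) {
    D[i, j] <- D[j, i] <-
      pairwise_distance(msa$seqs[i], msa$seqs[j], model, d_max)
  }
  D
}

#' Neighbor-joining tree from a distance matrix
#'
#' Standard neighbor joining (via [ape::nj()]); negative estimated branch
#' lengths are clamped to zero. This is the built-in topology fallback when
#' no tree is supplied; it recovers additive distance matrices exactly.
#'
#' @param D Symmetric non-negative distance matrix (>= 3 taxa).
#' @return Unrooted [ape::phylo] tree.
#' @export
nj_tree <- function(D) {
  D <- as.matrix(D)
  if (nrow(D) < 3) stop("need at least 3 taxa for neighbor joining")
  if (!isSymmetric(unname(D), tol = 1e-8))
    stop("distance matrix is not symmetric")
  if (any(D < 0)) stop("distance matrix has negative entries")
  tr <- ape::nj(D)
  tr$edge.length[tr$edge.length < 0] <- 0
  tr
}

#' Optimize branch lengths on a fixed topology
#'
#' Coordinate ascent: each branch in turn is optimized by Brent's method
#' (1-D) holding the others fixed, sweeping until the total log-likelihood
#' improves by less than `tol`. The log-likelihood is non-decreasing across
#' sweeps. For a two-sequence tree the result equals the pairwise ML
#' distance.
#'
#' @param tree [ape::phylo] with starting branch lengths.
#' @param msa Aligned [seq_set()].
#' @param model A [subst_model()].
#' @param tol Convergence tolerance on log-likelihood (default 1e-6).
#' @param max_sweeps Maximum passes over all branches (default 20).
#' @param b_max Upper bound per branch (default 10).
#' @return The tree with optimized `edge.length` and attribute `loglik`.
#' @export
optimize_branch_lengths <- function(tree, msa, model, tol = 1e-6,
                                    max_sweeps = 20, b_max = 10) {
  validate_tree(tree)
  cp <- compress_patterns(msa, tree$tip.label, model)
  ll <- function(tr) sum(cp$weights * pattern_loglik(tr, cp, model))
  fast <- length(model$rates) == 1L
  cur <- ll(tree)
  for (sweep in seq_len(max_sweeps)) {
    prev <- cur
    for (e in seq_len(nrow(tree$edge))) {
      if (fast) {
        # conditional likelihood of this branch given all others:
        # L(t) per pattern = sum_a A[a,] * (P(t) %*% F_child)[a,]
        # with A the rest-of-tree partial at the parent (excluding this
        # child's subtree). Per-pattern scale factors are constant in t.
        pl <- peel(tree, cp, model, model$rates[1])
        G <- down_messages(tree, pl, model)
        u <- tree$edge[e, 1]; c <- tree$edge[e, 2]
        A <- G[[u]]
        for (s in setdiff(tree$edge[tree$edge[, 1] == u, 2], c))
          A <- A * (pl$Pmats[[s]] %*% pl$partials[[s]])
        Fc <- pl$partials[[c]]
        f <- function(x) {
          P <- transition_matrix(model, x, model$rates[1])
          sum(cp$weights * log(pmax(colSums(A * (P %*% Fc)), 1e-300)))
        }
      } else {
        f <- function(x) {
          tr <- tree
          tr$edge.length[e] <- x
          ll(tr)
        }
      }
      opt <- optimize(f, interval = c(0, b_max), maximum = TRUE, tol = 1e-7)
      if (opt$objective >= f(tree$edge.length[e]))
        tree$edge.length[e] <- opt$maximum
    }
    cur <- ll(tree)
    if (cur - prev < tol) break
  }
  attr(tree, "loglik") <- cur
  tree
}
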