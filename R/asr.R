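## Ancestral sequence reconstruction.
##
## Marginal: for every internal node and site, the posterior distribution
## over states given all leaf data (up partials from pruning plus down
## messages from the rest of the tree). Joint: the single jointly most
## probable assignment of states to all internal nodes per site
## (max-product up-pass with backpointers, argmax down-pass).

# Down messages G[v] (nstates x npat), one rate category.
# G[root] = pi; for child c of u with siblings s:
#   G_c = t(P_c) %*% (G_u * prod_s (P_s %*% F_s))
down_messages <- function(tree, pl, model) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  npat <- ncol(pl$partials[[pl$root]])
  nstates <- length(model$states)
  G <- vector("list", nnode)
  G[[pl$root]] <- matrix(model$frequencies, nstates, npat)
  pr <- ape::reorder.phylo(tree, "postorder")
  # preorder = reversed postorder edge list
  edges <- pr$edge[rev(seq_len(nrow(pr$edge))), , drop = FALSE]
  # cache P %*% F per node
  PF <- vector("list", nnode)
  for (v in seq_len(nnode)) if (!is.null(pl$Pmats[[v]]))
    PF[[v]] <- pl$Pmats[[v]] %*% pl$partials[[v]]
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; c <- edges[e, 2]
    if (c <= ntip) next
    sibs <- setdiff(pr$edge[pr$edge[, 1] == u, 2], c)
    acc <- G[[u]]
    for (s in sibs) acc <- acc * PF[[s]]
    g <- crossprod(pl$Pmats[[c]], acc)   # t(P_c) %*% acc
    sc <- apply(g, 2, max); sc[sc == 0] <- 1
    G[[c]] <- sweep(g, 2, sc, "/")
  }
  G
}

#' Marginal ancestral sequence reconstruction
#'
#' For each internal node and alignment column, computes the posterior
#' distribution over states given the leaf data (message passing up and down
#' the rooted tree), the maximum-a-posteriori (MAP) state and its posterior
#' probability, and the runner-up state for tie reporting. With
#' discrete-gamma rate variation, posteriors are mixed over categories
#' weighted by each category's site likelihood. A node-site is flagged as a
#' gap when more than half of its descendant leaves are gapped there
#' (majority rule); flagged sites are excluded from residue calls.
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param msa Aligned [seq_set()] covering all leaves.
#' @param model A [subst_model()].
#' @return An `ancestral_profile`: list with `node_ids`, `node_labels`,
#'   `posterior` (list of `nstates x nsites` matrices per node),
#'   `map_state`, `map_posterior`, `second_state`, `second_posterior`
#'   (matrices nodes x sites), `gap_flag`, `states`, `tree`.
#' @export
marginal_asr <- function(tree, msa, model) {
  validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted for ancestral reconstruction; ",
         "root it first (e.g. with an outgroup via ape::root)")
  stopifnot(inherits(msa, "seq_set"), msa$aligned)
  tree <- label_nodes(tree, keep = TRUE)
  cp <- compress_patterns(msa, tree$tip.label, model)
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  nstates <- length(model$states)
  k <- length(model$rates)
  # per category: posteriors and per-pattern log-likelihood
  post_k <- vector("list", k)
  ll_k <- matrix(0, cp$npat, k)
  for (i in seq_len(k)) {
    pl <- peel(tree, cp, model, model$rates[i])
    G <- down_messages(tree, pl, model)
    ll_k[, i] <- log(as.vector(model$frequencies %*%
                                 pl$partials[[pl$root]])) + pl$logscale
    post_k[[i]] <- lapply(internal, function(v) {
      p <- pl$partials[[v]] * G[[v]]
      sweep(p, 2, colSums(p), "/")
    })
  }
  mx <- apply(ll_k, 1, max)
  w <- exp(ll_k - mx)
  w <- w / rowSums(w)                 # pattern x category mixture weights
  posterior <- lapply(seq_along(internal), function(vi) {
    p <- matrix(0, nstates, cp$npat)
    for (i in seq_len(k)) p <- p + sweep(post_k[[i]][[vi]], 2, w[, i], "*")
    p[, cp$site_to_pattern, drop = FALSE]
  })
  nsites <- length(cp$site_to_pattern)
  nint <- length(internal)
  map_state <- second_state <- matrix("", nint, nsites)
  map_post <- second_post <- matrix(0, nint, nsites)
  for (vi in seq_len(nint)) {
    p <- posterior[[vi]]
    i1 <- max.col(t(p), ties.method = "first")
    map_state[vi, ] <- model$states[i1]
    map_post[vi, ] <- p[cbind(i1, seq_len(nsites))]
    p2 <- p; p2[cbind(i1, seq_len(nsites))] <- -1
    i2 <- max.col(t(p2), ties.method = "first")
    second_state[vi, ] <- model$states[i2]
    second_post[vi, ] <- p[cbind(i2, seq_len(nsites))]
  }
  labels <- node_labels(tree)[internal]
  dimnames(map_state) <- dimnames(map_post) <-
    dimnames(second_state) <- dimnames(second_post) <-
    list(labels, NULL)
  names(posterior) <- labels
  structure(list(node_ids = internal, node_labels = labels,
                 posterior = posterior, map_state = map_state,
                 map_posterior = map_post, second_state = second_state,
                 second_posterior = second_post,
                 gap_flag = gap_flags(tree, msa)[labels, , drop = FALSE],
                 states = model$states, tree = tree),
            class = "ancestral_profile")
}

#' @export
print.ancestral_profile <- function(x, ...) {
  cat(sprintf("ancestral_profile: %d internal nodes x %d sites (%d states)\n",
              length(x$node_ids), ncol(x$map_state), length(x$states)))
  invisible(x)
}

# majority-rule gap flags for internal nodes (nodes x sites, labeled rows)
gap_flags <- function(tree, msa) {
  m <- seq_matrix(msa)[tree$tip.label, , drop = FALSE] == "-"
  ntip <- length(tree$tip.label)
  internal <- (ntip + 1L):(ntip + tree$Nnode)
  out <- matrix(FALSE, length(internal), ncol(m),
                dimnames = list(node_labels(tree)[internal], NULL))
  for (k in seq_along(internal)) {
    tips <- descendant_tips(tree, internal[k])
    out[k, ] <- colMeans(m[tips, , drop = FALSE]) > 0.5
  }
  out
}

#' Joint ancestral sequence reconstruction
#'
#' Computes the single assignment of states to all internal nodes that
#' maximizes the joint probability per site (dynamic programming in log
#' space: max-product up-pass with backpointers, argmax down-pass). With
#' rate categories, the category maximizing the joint probability is chosen
#' per site.
#'
#' @inheritParams marginal_asr
#' @return Named character vector: internal node label -> reconstructed
#'   sequence (gap-flagged sites are written as `-`).
#' @export
joint_asr <- function(tree, msa, model) {
  validate_tree(tree)
  if (!ape::is.rooted(tree))
    stop("tree must be rooted for ancestral reconstruction; ",
         "root it first (e.g. with an outgroup via ape::root)")
  tree <- label_nodes(tree, keep = TRUE)
  cp <- compress_patterns(msa, tree$tip.label, model)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nstates <- length(model$states)
  k <- length(model$rates)
  best <- NULL
  for (ki in seq_len(k)) {
    res <- joint_onerate(tree, cp, model, model$rates[ki])
    if (is.null(best)) {
      best <- res
    } else {
      better <- res$score > best$score
      best$score[better] <- res$score[better]
      best$assign[, better] <- res$assign[, better]
    }
  }
  internal <- (ntip + 1L):nnode
  labels <- node_labels(tree)[internal]
  gf <- gap_flags(tree, msa)
  out <- vapply(seq_along(internal), function(vi) {
    chars <- model$states[best$assign[vi, cp$site_to_pattern]]
    chars[gf[labels[vi], ]] <- "-"
    paste(chars, collapse = "")
  }, character(1))
  setNames(out, labels)
}

# max-product over one rate category; returns per-pattern best score and
# internal-node assignments (rows = internal nodes in node-number order)
joint_onerate <- function(tree, cp, model, rate) {
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  nstates <- length(model$states)
  npat <- cp$npat
  po <- ape::reorder.phylo(tree, "postorder")
  logP <- vector("list", nnode)
  for (e in seq_len(nrow(po$edge))) {
    child <- po$edge[e, 2]
    logP[[child]] <- log(pmax(transition_matrix(model, po$edge.length[e],
                                                rate), 1e-300))
  }
  M <- vector("list", nnode)    # M[v]: nstates(parent) x npat best log-prob
  BP <- vector("list", nnode)   # backpointers, same shape
  W <- vector("list", nnode)    # sum of children M at each internal node
  for (v in seq_len(ntip)) {
    tp <- log(pmax(cp$tip_partials[[tree$tip.label[v]]], 1e-300))
    M[[v]] <- matrix(0, nstates, npat)
    BP[[v]] <- matrix(0L, nstates, npat)
    for (a in seq_len(nstates)) {
      sc <- logP[[v]][a, ] + tp          # nstates x npat
      bp <- max.col(t(sc), ties.method = "first")
      M[[v]][a, ] <- sc[cbind(bp, seq_len(npat))]
      BP[[v]][a, ] <- bp
    }
  }
  parents <- unique(po$edge[, 1])
  root <- ntip + 1L
  for (v in parents) {
    kids <- po$edge[po$edge[, 1] == v, 2]
    Wv <- matrix(0, nstates, npat)
    for (c in kids) Wv <- Wv + M[[c]]
    W[[v]] <- Wv
    if (v == root) break
    M[[v]] <- matrix(0, nstates, npat)
    BP[[v]] <- matrix(0L, nstates, npat)
    for (a in seq_len(nstates)) {
      sc <- logP[[v]][a, ] + Wv
      bp <- max.col(t(sc), ties.method = "first")
      M[[v]][a, ] <- sc[cbind(bp, seq_len(npat))]
      BP[[v]][a, ] <- bp
    }
  }
  # root choice
  sc <- log(model$frequencies) + W[[root]]
  xroot <- max.col(t(sc), ties.method = "first")
  score <- sc[cbind(xroot, seq_len(npat))]
  assign <- matrix(0L, tree$Nnode, npat)
  assign[root - ntip, ] <- xroot
  # preorder down-pass
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; c <- edges[e, 2]
    if (c <= ntip) next
    pa <- assign[u - ntip, ]
    assign[c - ntip, ] <- BP[[c]][cbind(pa, seq_len(npat))]
  }
  list(score = score, assign = assign)
}

#' Extract residues at key structural positions
#'
#' Reads out the residue matrix at a set of BW-labeled alignment columns,
#' for extant sequences ([seq_set()]) or reconstructed ancestors
#' ([marginal_asr()] profile). For ancestors the MAP residue and its
#' posterior are reported; when the top two posteriors differ by less than
#' `tie_delta` the call is reported as `"X/Y"` (both states), mirroring
#' dual predictions at highly variable positions.
#'
#' @param x A `seq_set` or `ancestral_profile`.
#' @param bwmap A [map_bw_numbers()] result.
#' @param labels BW labels to extract.
#' @param tie_delta Posterior gap below which the runner-up is co-reported.
#' @return Data frame: rows = sequences/nodes, columns = labels, cells =
#'   residues (possibly `"X/Y"`). For profiles, attribute `"posterior"`
#'   holds the matching matrix of MAP posteriors.
#' @export
extract_key_residues <- function(x, bwmap, labels, tie_delta = 0.05) {
  cols <- bw_columns(bwmap, labels) + 1L   # to 1-based
  if (inherits(x, "seq_set")) {
    m <- seq_matrix(x)[, cols, drop = FALSE]
    df <- as.data.frame(m, stringsAsFactors = FALSE)
    dimnames(df) <- list(x$ids, labels)
    return(df)
  }
  stopifnot(inherits(x, "ancestral_profile"))
  res <- x$map_state[, cols, drop = FALSE]
  pp <- x$map_posterior[, cols, drop = FALSE]
  sec <- x$second_state[, cols, drop = FALSE]
  spp <- x$second_posterior[, cols, drop = FALSE]
  gf <- x$gap_flag[, cols, drop = FALSE]
  tie <- (pp - spp) < tie_delta
  res[tie] <- paste(res[tie], sec[tie], sep = "/")
  res[gf] <- "-"
  df <- as.data.frame(res, stringsAsFactors = FALSE)
  dimnames(df) <- list(x$node_labels, labels)
  dimnames(pp) <- dimnames(df)
  attr(df, "posterior") <- pp
  df
}

#' Write a key-residue matrix in report layout
#'
#' Rows are BW labels, columns are taxa/nodes, cells `R` or `R(0.97)` when
#' posteriors are attached.
#'
#' @param key_df Result of [extract_key_residues()].
#' @param path Output TSV path.
#' @return The path, invisibly.
#' @export
write_key_matrix <- function(key_df, path) {
  pp <- attr(key_df, "posterior")
  m <- t(as.matrix(key_df))
  if (!is.null(pp)) {
    fmt <- t(matrix(sprintf("%s(%.2f)", as.matrix(key_df), pp),
                    nrow = nrow(key_df), dimnames = dimnames(key_df)))
    m <- fmt
  }
  df <- data.frame(bw_label = rownames(m), m, check.names = FALSE,
                   stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
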