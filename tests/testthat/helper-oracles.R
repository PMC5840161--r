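# Independent brute-force oracles and shared scenario builders.

# Exhaustive-enumeration likelihood/ASR oracle for small rooted trees:
# sums over every assignment of states to internal nodes. Independent of
# the pruning implementation (direct product over edges).
enum_oracle <- function(tree, msa, model) {
  states <- model$states
  n <- length(states)
  ntip <- length(tree$tip.label)
  nint <- tree$Nnode
  stopifnot(n^nint <= 2e5)
  chars <- do.call(rbind, strsplit(msa$seqs[tree$tip.label], ""))
  nsites <- ncol(chars)
  P <- lapply(seq_len(nrow(tree$edge)), function(e)
    transition_matrix(model, tree$edge.length[e]))
  combos <- as.matrix(expand.grid(rep(list(seq_len(n)), nint)))
  root_col <- 1L  # internal node ntip+1 is column 1
  lik <- matrix(0, nrow(combos), nsites)
  for (s in seq_len(nsites)) {
    pr <- model$frequencies[combos[, root_col]]
    for (e in seq_len(nrow(tree$edge))) {
      u <- tree$edge[e, 1]; v <- tree$edge[e, 2]
      pu <- combos[, u - ntip]
      if (v > ntip) {
        pr <- pr * P[[e]][cbind(pu, combos[, v - ntip])]
      } else {
        x <- match(chars[v, s], states)
        if (!is.na(x)) pr <- pr * P[[e]][cbind(pu, x)]
        # gap/unknown tip contributes a factor of 1
      }
    }
    lik[, s] <- pr
  }
  sitelik <- colSums(lik)
  marginal <- lapply(seq_len(nint), function(k) {
    post <- vapply(seq_len(n), function(st)
      colSums(lik[combos[, k] == st, , drop = FALSE]), numeric(nsites))
    t(post) / rep(sitelik, each = n)
  })
  joint <- vapply(seq_len(nsites), function(s)
    combos[which.max(lik[, s]), ], integer(nint))
  list(site_loglik = log(sitelik), marginal = marginal,
       joint = matrix(states[joint], nrow = nint))
}

# edge indices of the clade below internal node v
subtree_edges <- function(tr, v) {
  kids <- which(tr$edge[, 1] == v)
  out <- integer(0)
  repeat {
    if (!length(kids)) break
    out <- c(out, kids)
    nxt <- which(tr$edge[, 1] %in% tr$edge[kids, 2])
    kids <- setdiff(nxt, out)
  }
  out
}

# 20-taxon time tree with a clade-heritable rate shift: one clade evolves
# at mult_fast, the rest at 1 (the classic two-rate-class model). Branch
# lengths are the exact expectations (long-sequence limit).
two_class_rate_tree <- function(seed = 3, n_taxa = 20, mult_fast = 3) {
  set.seed(seed)
  tr <- ape::rcoal(n_taxa)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr))
  ntip <- n_taxa
  # the largest clade covering 6-14 edges becomes the fast class
  cands <- (ntip + 2):(ntip + tr$Nnode)
  sizes <- vapply(cands, function(v) length(subtree_edges(tr, v)),
                  integer(1))
  ok <- cands[sizes >= 6 & sizes <= 14]
  v <- ok[which.max(sizes[match(ok, cands)])]
  mult <- rep(1, nrow(tr$edge))
  mult[c(subtree_edges(tr, v), which(tr$edge[, 2] == v))] <- mult_fast
  bt <- tr
  bt$edge.length <- tr$edge.length * mult
  list(tree = bt, time_tree = tr, mult = mult)
}

# truth vector aligned to relative_rates() branch order (postorder)
match_branch_truth <- function(tree, rt, mult) {
  po <- ape::reorder.phylo(tree, "postorder")
  mult[match(paste(po$edge[, 1], po$edge[, 2]),
             paste(tree$edge[, 1], tree$edge[, 2]))]
}

# random coalescent tree scaled to a given height
scaled_coal <- function(n, height, seed) {
  set.seed(seed)
  tr <- ape::rcoal(n)
  tr$edge.length <- tr$edge.length / max(ape::node.depth.edgelength(tr)) *
    height
  tr
}

# random protein seq_set
random_seqset <- function(n = 5, len = 30, seed = 1) {
  set.seed(seed)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  seqs <- vapply(seq_len(n), function(i)
    paste(sample(aas, len, replace = TRUE), collapse = ""), character(1))
  seq_set(setNames(seqs, paste0("s", seq_len(n))), aligned = TRUE)
}
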