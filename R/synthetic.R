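## Sequence simulators with recorded ancestral truth. Protein states are
## drawn through exact transition probabilities per branch; codons evolve by
## Gillespie simulation so that true synonymous/nonsynonymous event counts
## are available to validate the selection module.

#' Simulation configuration
#'
#' @param tree Rooted [ape::phylo] tree with branch lengths.
#' @param model A [subst_model()] (protein simulation).
#' @param n_sites Number of sites (>= 1).
#' @param seed Integer seed; a fixed seed gives byte-identical output.
#' @param lineage_rate_multipliers Optional numeric vector, one positive
#'   multiplier per tree edge (in `tree$edge` order).
#' @return A `sim_config` list.
#' @export
sim_config <- function(tree, model, n_sites, seed = 1L,
                       lineage_rate_multipliers = NULL) {
  validate_tree(tree)
  stopifnot(n_sites >= 1)
  if (!is.null(lineage_rate_multipliers)) {
    stopifnot(length(lineage_rate_multipliers) == nrow(tree$edge),
              all(lineage_rate_multipliers > 0))
  }
  structure(list(tree = tree, model = model, n_sites = as.integer(n_sites),
                 seed = as.integer(seed),
                 lineage_rate_multipliers = lineage_rate_multipliers),
            class = "sim_config")
}

#' Simulate protein evolution along a tree
#'
#' The root sequence is drawn from the model's equilibrium frequencies and
#' evolved along each branch by sampling from the exact transition matrix
#' `P(b * multiplier)`. With discrete-gamma rate variation each site is
#' assigned a rate category at the root. All internal node sequences (the
#' ancestral truth) are returned alongside the leaf alignment.
#'
#' @param config A [sim_config()].
#' @return List with `msa` (aligned [seq_set()] of leaves) and
#'   `true_ancestors` (named character vector, internal node label ->
#'   sequence).
#' @export
simulate_protein <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  tree <- label_nodes(config$tree, keep = TRUE)
  model <- config$model
  n <- config$n_sites
  set.seed(config$seed)
  nstates <- length(model$states)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  site_rates <- model$rates[sample.int(length(model$rates), n,
                                       replace = TRUE)]
  states <- matrix(0L, nnode, n)
  root <- ntip + 1L
  states[root, ] <- sample.int(nstates, n, replace = TRUE,
                               prob = model$frequencies)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]  # preorder
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  mult <- rep(1, nrow(tree$edge))
  if (!is.null(config$lineage_rate_multipliers)) {
    # multipliers are in tree$edge order; remap to the preorder walk
    key <- paste(tree$edge[, 1], tree$edge[, 2])
    mult <- config$lineage_rate_multipliers[
      match(paste(edges[, 1], edges[, 2]), key)]
  }
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    for (r in unique(site_rates)) {
      idx <- which(site_rates == r)
      P <- transition_matrix(model, elens[e] * mult[e], r)
      cum <- t(apply(P, 1, cumsum))
      uvals <- runif(length(idx))
      from <- states[u, idx]
      states[v, idx] <- vapply(seq_along(idx), function(i)
        sum(cum[from[i], ] < uvals[i]) + 1L, integer(1))
    }
  }
  labs <- node_labels(tree)
  to_seq <- function(i) paste(model$states[states[i, ]], collapse = "")
  leaves <- setNames(vapply(seq_len(ntip), to_seq, character(1)),
                     tree$tip.label)
  anc <- setNames(vapply((ntip + 1L):nnode, to_seq, character(1)),
                  labs[(ntip + 1L):nnode])
  alphabet <- if (nstates == 4) "dna" else "protein"
  list(msa = seq_set(leaves, aligned = TRUE, alphabet = alphabet),
       true_ancestors = anc)
}

# Muse-Gaut style codon rate rows: rates from codon `ci` to its one-step
# neighbors; kappa scales transitions, omega scales nonsynonymous changes.
codon_neighbors <- function() {
  sense <- sense_codons()
  gc <- genetic_code()
  nb <- lapply(sense, function(cd) {
    chars <- strsplit(cd, "")[[1]]
    out <- list()
    for (pos in 1:3) for (nt in setdiff(NT_STATES, chars[pos])) {
      mut <- chars; mut[pos] <- nt
      mcd <- paste(mut, collapse = "")
      if (gc[[mcd]] == "*") next
      ts <- paste(sort(c(chars[pos], nt)), collapse = "") %in% c("AG", "CT")
      out[[length(out) + 1L]] <- list(to = mcd, transition = ts,
                                      syn = gc[[mcd]] == gc[[cd]])
    }
    out
  })
  names(nb) <- sense
  nb
}

#' Simulate codon evolution with per-site dN/dS
#'
#' Gillespie simulation over the 61 sense codons: a change to a one-step
#' neighbor occurs at rate `kappa^(is transition) * omega_site^(is
#' nonsynonymous)`, and the generator is rescaled so the neutral
#' (`omega = 1`) expected rate is 1 substitution per codon site per unit
#' branch length. True ancestral codons and the per-site counts of true
#' synonymous/nonsynonymous events are recorded.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param omega Numeric vector of per-site dN/dS values (length = number of
#'   codon sites).
#' @param kappa Transition/transversion rate ratio (default 2).
#' @param seed Integer seed.
#' @return List with `msa` (leaf DNA [seq_set()]), `true_ancestors`
#'   (named DNA sequences), `omega`, and `true_counts` (data frame per site:
#'   `syn_events`, `nonsyn_events`).
#' @export
simulate_codon <- function(tree, omega, kappa = 2, seed = 1L) {
  validate_tree(tree)
  stopifnot(all(omega >= 0))
  tree <- label_nodes(tree, keep = TRUE)
  set.seed(as.integer(seed))
  nsites <- length(omega)
  sense <- sense_codons()
  nb <- codon_neighbors()
  # neutral scaling: mean total leaving rate at omega = 1, uniform codons
  leave1 <- vapply(nb, function(x)
    sum(vapply(x, function(n) if (n$transition) kappa else 1, numeric(1))),
    numeric(1))
  scale <- mean(leave1)
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  states <- matrix("", nnode, nsites)
  states[root, ] <- sample(sense, nsites, replace = TRUE)
  syn_events <- nonsyn_events <- numeric(nsites)
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    for (s in seq_len(nsites)) {
      cur <- states[u, s]
      t_left <- elens[e]
      repeat {
        rates <- vapply(nb[[cur]], function(n)
          (if (n$transition) kappa else 1) *
            (if (n$syn) 1 else omega[s]), numeric(1)) / scale
        tot <- sum(rates)
        if (tot <= 0) break
        wait <- rexp(1, tot)
        if (wait > t_left) break
        t_left <- t_left - wait
        pick <- sample.int(length(rates), 1, prob = rates)
        if (nb[[cur]][[pick]]$syn) syn_events[s] <- syn_events[s] + 1
        else nonsyn_events[s] <- nonsyn_events[s] + 1
        cur <- nb[[cur]][[pick]]$to
      }
      states[v, s] <- cur
    }
  }
  labs <- node_labels(tree)
  to_seq <- function(i) paste(states[i, ], collapse = "")
  leaves <- setNames(vapply(seq_len(ntip), to_seq, character(1)),
                     tree$tip.label)
  anc <- setNames(vapply((ntip + 1L):nnode, to_seq, character(1)),
                  labs[(ntip + 1L):nnode])
  list(msa = seq_set(leaves, aligned = TRUE, alphabet = "dna"),
       true_ancestors = anc, omega = omega,
       true_counts = data.frame(site = seq_len(nsites),
                                syn_events = syn_events,
                                nonsyn_events = nonsyn_events))
}

#' Simulate binder gain/loss history along a tree
#'
#' Key-position residues evolve by a Markov jump process: at rate
#' `switch_rate` per unit branch length a position jumps to a uniformly
#' chosen alternative among its rule-listed substitutions and the key
#' residues of both modes. The binder verdict is computed at every node
#' with [classify_binder()], giving ground truth for convergent
#' gain/loss scenarios. Substitutions can be forced onto specific branches.
#'
#' @param tree Rooted [ape::phylo] tree.
#' @param catalog A [load_catalog()] result.
#' @param switch_rate Non-negative jump rate per position.
#' @param seed Integer seed.
#' @param root_profile Named residue map for the root (default: the
#'   bundled hT2R10 profile).
#' @param forced Optional named list: `"parent_label->child_label"` ->
#'   named character vector of label -> residue applied on that branch.
#' @return List with `residues` (named list of per-node residue maps) and
#'   `verdicts` (named character vector per node).
#' @export
simulate_binder_history <- function(tree, catalog, switch_rate = 0.1,
                                    seed = 1L,
                                    root_profile = residue_map("hT2R10"),
                                    forced = NULL) {
  validate_tree(tree)
  stopifnot(switch_rate >= 0)
  tree <- label_nodes(tree, keep = TRUE)
  set.seed(as.integer(seed))
  labs <- node_labels(tree)
  labels <- unique(catalog$label)
  # alternative residues per position: key residues of both modes plus any
  # explicitly rule-listed substitutions
  alts <- lapply(labels, function(l) {
    rows <- which(catalog$label == l)
    listed <- unlist(lapply(catalog$rules[rows], function(rs)
      unlist(lapply(rs, function(r)
        if (!is.null(r$residues)) strsplit(r$residues, "")[[1]]))))
    unique(c(catalog$key_residue[rows], listed))
  })
  names(alts) <- labels
  ntip <- length(tree$tip.label)
  nnode <- ntip + tree$Nnode
  root <- ntip + 1L
  profiles <- vector("list", nnode)
  profiles[[root]] <- root_profile[labels]
  po <- ape::reorder.phylo(tree, "postorder")
  edges <- po$edge[rev(seq_len(nrow(po$edge))), , drop = FALSE]
  elens <- po$edge.length[rev(seq_len(nrow(po$edge)))]
  for (e in seq_len(nrow(edges))) {
    u <- edges[e, 1]; v <- edges[e, 2]
    prof <- profiles[[u]]
    if (switch_rate > 0) {
      for (l in labels) {
        n_jumps <- stats::rpois(1, switch_rate * elens[e])
        for (j in seq_len(n_jumps)) {
          choices <- setdiff(alts[[l]], prof[[l]])
          if (length(choices))
            prof[[l]] <- sample(choices, 1)
        }
      }
    }
    key <- paste0(labs[u], "->", labs[v])
    if (!is.null(forced) && key %in% names(forced)) {
      f <- forced[[key]]
      prof[names(f)] <- f
    }
    profiles[[v]] <- prof
  }
  names(profiles) <- labs
  verdicts <- vapply(profiles, function(p)
    classify_binder(p, catalog)$verdict, character(1))
  list(residues = profiles, verdicts = verdicts)
}
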