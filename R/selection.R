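## Counting-based site-specific dN/dS (SLAC-style): expected synonymous and
## nonsynonymous site counts per codon by one-step enumeration (NG86
## convention), observed changes summed over branches between reconstructed
## codon endpoints, minimal mutational paths averaged, and a per-site
## binomial test of the nonsynonymous proportion against its neutral
## expectation.

#' Expected synonymous/nonsynonymous site counts of one codon
#'
#' Enumerates the nine single-nucleotide changes of a sense codon. Each
#' position contributes `(# synonymous changes)/3` synonymous and
#' `(# nonsynonymous changes)/3` nonsynonymous sites; changes to stop codons
#' are excluded, so `S + N = 3` minus the stop-change fraction.
#'
#' @param codon 3-letter codon string (sense codon, standard code).
#' @return Named numeric: `S_sites`, `N_sites`.
#' @export
#' @examples
#' ng86_site_counts("TTT")  # S = 1/3
ng86_site_counts <- function(codon) {
  codon <- toupper(codon)
  gc <- genetic_code()
  if (!codon %in% names(gc) || grepl("[^ACGT]", codon))
    stop("not an unambiguous codon: ", codon)
  aa <- gc[[codon]]
  if (aa == "*") stop("stop codon has undefined site counts: ", codon)
  chars <- strsplit(codon, "")[[1]]
  S <- N <- 0
  for (pos in 1:3) for (nt in setdiff(NT_STATES, chars[pos])) {
    mut <- chars; mut[pos] <- nt
    maa <- gc[[paste(mut, collapse = "")]]
    if (maa == "*") next
    if (maa == aa) S <- S + 1 / 3 else N <- N + 1 / 3
  }
  c(S_sites = S, N_sites = N)
}

# Average syn/nonsyn step counts between two codons over all minimal
# mutational paths that avoid stop codons (all paths if every path hits a
# stop). Returns c(syn, nonsyn).
codon_path_counts <- function(c1, c2) {
  gc <- genetic_code()
  a <- strsplit(c1, "")[[1]]; b <- strsplit(c2, "")[[1]]
  diff <- which(a != b)
  nd <- length(diff)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(diff) else
    if (nd == 2L) list(diff, rev(diff)) else
      lapply(list(c(1,2,3), c(1,3,2), c(2,1,3), c(2,3,1), c(3,1,2),
                  c(3,2,1)), function(o) diff[o])
  count_path <- function(order) {
    cur <- a; s <- 0; n <- 0
    for (pos in order) {
      nxt <- cur; nxt[pos] <- b[pos]
      aa1 <- gc[[paste(cur, collapse = "")]]
      aa2 <- gc[[paste(nxt, collapse = "")]]
      if (aa2 == "*" || aa1 == "*") return(NULL)
      if (aa1 == aa2) s <- s + 1 else n <- n + 1
      cur <- nxt
    }
    c(s, n)
  }
  res <- Filter(Negate(is.null), lapply(perms, count_path))
  if (!length(res)) {
    # every minimal path passes a stop; fall back to counting all paths
    # with stop steps treated as nonsynonymous
    res <- lapply(perms, function(order) {
      cur <- a; s <- 0; n <- 0
      for (pos in order) {
        nxt <- cur; nxt[pos] <- b[pos]
        if (gc[[paste(cur, collapse = "")]] ==
            gc[[paste(nxt, collapse = "")]]) s <- s + 1 else n <- n + 1
        cur <- nxt
      }
      c(s, n)
    })
  }
  m <- colMeans(do.call(rbind, res))
  c(syn = m[1], nonsyn = m[2])
}

# split a DNA sequence into codons
split_codons <- function(seq) {
  n <- nchar(seq)
  if (n %% 3 != 0) stop("sequence length not divisible by 3")
  substring(seq, seq(1, n, 3), seq(3, n, 3))
}

#' Reconstruct ancestral codon sequences on a tree
#'
#' Joint ancestral reconstruction at the nucleotide level (equal-rate
#' 4-state model) assembled into codons: the standard preprocessing step for
#' counting-based selection analysis.
#'
#' @param codon_msa Aligned DNA [seq_set()], length divisible by 3.
#' @param tree Rooted [ape::phylo] covering the alignment ids.
#' @return Named character vector: internal node label -> DNA sequence.
#' @export
ancestral_codons <- function(codon_msa, tree) {
  stopifnot(inherits(codon_msa, "seq_set"), codon_msa$alphabet == "dna")
  joint_asr(tree, codon_msa, subst_model("nucleotide"))
}

#' Site-specific dN/dS from a codon alignment
#'
#' For every codon site, observed synonymous (`Sd`) and nonsynonymous
#' (`Nd`) changes are summed over all branches between reconstructed
#' endpoint codons (minimal mutational paths averaged, stop-free paths
#' preferred); expected site counts `S_sites`/`N_sites` are the NG86 counts
#' averaged over the codons observed at the site across all nodes. The
#' ratio `omega = (Nd/N_sites)/(Sd/S_sites)` (infinite when `Sd = 0` with
#' `Nd > 0`, undefined when the site has no changes) is tested per site by
#' a two-sided binomial test of `Nd` among `Nd + Sd` changes against the
#' neutral proportion `N_sites/(N_sites + S_sites)` (fractional counts are
#' kept fractional; the test is the large-sample score form so fractional
#' counts need no rounding). Sites are classified `positive` (`omega > 1`,
#' `p < alpha`), `purifying` (`omega < 1`, `p < alpha`), else `neutral`
#' (`undefined` for sites with unresolvable codons).
#'
#' @param codon_msa Aligned DNA [seq_set()], length divisible by 3, no
#'   internal stops in any reading frame 1 codon.
#' @param tree Rooted [ape::phylo] tree.
#' @param ancestors Optional named vector of ancestral DNA sequences
#'   (internal node label -> sequence); computed with [ancestral_codons()]
#'   when omitted.
#' @param alpha Significance level for classification (default 0.05).
#' @param adjust If `TRUE`, Benjamini-Hochberg adjust p-values across sites
#'   before classification.
#' @return Data frame (class `site_selection_table`): `site`, `N_sites`,
#'   `S_sites`, `Nd`, `Sd`, `omega`, `p_value`, `class`.
#' @export
site_dnds <- function(codon_msa, tree, ancestors = NULL, alpha = 0.05,
                      adjust = FALSE) {
  stopifnot(inherits(codon_msa, "seq_set"), codon_msa$aligned,
            codon_msa$alphabet == "dna")
  validate_tree(tree)
  tree <- label_nodes(tree, keep = TRUE)
  if (is.null(ancestors)) ancestors <- ancestral_codons(codon_msa, tree)
  labs <- node_labels(tree)
  seqs <- c(codon_msa$seqs, ancestors)
  codons <- lapply(seqs, split_codons)
  nsites <- length(codons[[1]])
  gc <- genetic_code()
  sense <- sense_codons()
  # expected sites per codon (cached over the 61 sense codons)
  site_tab <- t(vapply(sense, ng86_site_counts, numeric(2)))
  edges <- tree$edge
  Nd <- Sd <- numeric(nsites)
  for (e in seq_len(nrow(edges))) {
    p <- labs[edges[e, 1]]; c <- labs[edges[e, 2]]
    cp <- codons[[p]]; cc <- codons[[c]]
    for (s in seq_len(nsites)) {
      if (cp[s] == cc[s]) next
      if (grepl("[^ACGT]", cp[s]) || grepl("[^ACGT]", cc[s])) next
      cnt <- codon_path_counts(cp[s], cc[s])
      Sd[s] <- Sd[s] + cnt[["syn"]]
      Nd[s] <- Nd[s] + cnt[["nonsyn"]]
    }
  }
  N_sites <- S_sites <- numeric(nsites)
  undefined <- logical(nsites)
  for (s in seq_len(nsites)) {
    obs <- vapply(codons, `[[`, character(1), s)
    obs <- obs[obs %in% sense]
    if (!length(obs)) { undefined[s] <- TRUE; next }
    S_sites[s] <- mean(site_tab[obs, "S_sites"])
    N_sites[s] <- mean(site_tab[obs, "N_sites"])
  }
  omega <- rep(NA_real_, nsites)
  p_value <- rep(1, nsites)
  cls <- rep("neutral", nsites)
  for (s in seq_len(nsites)) {
    if (undefined[s]) { cls[s] <- "undefined"; next }
    if (Nd[s] + Sd[s] == 0) next                  # no changes: neutral, NA omega
    dn <- Nd[s] / N_sites[s]
    ds <- if (S_sites[s] > 0) Sd[s] / S_sites[s] else NA_real_
    omega[s] <- if (!is.na(ds) && ds > 0) dn / ds else
      if (Nd[s] > 0) Inf else 0
    # two-sided binomial proportion (score) test on the fractional counts
    n <- Nd[s] + Sd[s]
    p0 <- N_sites[s] / (N_sites[s] + S_sites[s])
    z <- (Nd[s] - n * p0) / sqrt(n * p0 * (1 - p0))
    p_value[s] <- 2 * stats::pnorm(-abs(z))
  }
  padj <- if (adjust) stats::p.adjust(p_value, "BH") else p_value
  sig <- padj < alpha & !undefined & (Nd + Sd) > 0
  cls[sig & !is.na(omega) & omega > 1] <- "positive"
  cls[sig & !is.na(omega) & omega < 1] <- "purifying"
  out <- data.frame(site = seq_len(nsites), N_sites = N_sites,
                    S_sites = S_sites, Nd = Nd, Sd = Sd, omega = omega,
                    p_value = p_value, class = cls,
                    stringsAsFactors = FALSE)
  class(out) <- c("site_selection_table", "data.frame")
  out
}

#' Join BW labels onto a site selection table
#'
#' Codon site `i` corresponds to protein alignment column `i`; sites whose
#' column carries a BW label get that label, others `NA`.
#'
#' @param table A [site_dnds()] result.
#' @param bwmap A [map_bw_numbers()] result over the matching protein MSA.
#' @return The table with a `bw_label` column.
#' @export
join_bw_labels <- function(table, bwmap) {
  lab <- rep(NA_character_, nrow(table))
  cols0 <- as.integer(names(bwmap$column_to_label))
  hit <- cols0 + 1L
  keep <- hit >= 1 & hit <= nrow(table)
  lab[hit[keep]] <- unname(bwmap$column_to_label)[keep]
  table$bw_label <- lab
  table
}
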