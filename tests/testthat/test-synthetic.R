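test_that("simulators are deterministic under a fixed seed", {
  tr <- scaled_coal(8, 0.8, seed = 50)
  m <- subst_model("empirical")
  a <- simulate_protein(sim_config(tr, m, 100, seed = 7))
  b <- simulate_protein(sim_config(tr, m, 100, seed = 7))
  expect_identical(a$msa$seqs, b$msa$seqs)
  expect_identical(a$true_ancestors, b$true_ancestors)
  c1 <- simulate_codon(tr, omega = rep(1, 30), seed = 7)
  c2 <- simulate_codon(tr, omega = rep(1, 30), seed = 7)
  expect_identical(c1$msa$seqs, c2$msa$seqs)
  expect_identical(c1$true_counts, c2$true_counts)
})

test_that("zero-length branches copy the root everywhere", {
  tr <- ape::read.tree(text = "((a:0,b:0):0,(c:0,d:0):0);")
  sim <- simulate_protein(sim_config(tr, subst_model("poisson_equal"),
                                     50, seed = 3))
  seqs <- c(sim$msa$seqs, sim$true_ancestors)
  expect_equal(length(unique(unname(seqs))), 1)
})

test_that("one-branch mismatch proportion matches the closed form", {
  m <- subst_model("poisson_equal")
  t <- 0.3
  tr <- ape::read.tree(text = sprintf("(a:%f,b:0);", t))
  n <- 1e5
  sim <- simulate_protein(sim_config(tr, m, n, seed = 8))
  p_obs <- mean(strsplit(sim$msa$seqs[["a"]], "")[[1]] !=
                  strsplit(sim$msa$seqs[["b"]], "")[[1]])
  p_true <- (19 / 20) * (1 - exp(-(20 / 19) * t))
  se <- sqrt(p_true * (1 - p_true) / n)
  expect_lt(abs(p_obs - p_true), 3 * se)
})

test_that("long-branch composition converges to the model equilibrium", {
  m <- subst_model("empirical")
  tr <- ape::read.tree(text = "(a:25,b:25);")
  sim <- simulate_protein(sim_config(tr, m, 20000, seed = 9))
  freq <- table(factor(strsplit(sim$msa$seqs[["a"]], "")[[1]],
                       levels = m$states)) / 20000
  expect_lt(max(abs(as.numeric(freq) - m$frequencies)), 0.01)
})

test_that("omega = 0 yields exclusively synonymous events", {
  tr <- scaled_coal(6, 2, seed = 51)
  sim <- simulate_codon(tr, omega = rep(0, 40), seed = 12)
  expect_true(all(sim$true_counts$nonsyn_events == 0))
  expect_gt(sum(sim$true_counts$syn_events), 0)
  # and the selection module sees it the same way
  tab <- site_dnds(sim$msa, tr)
  expect_true(all(tab$Nd == 0))
})

test_that("binder histories propagate verdicts along the tree", {
  cat_ <- load_catalog()
  tr <- ape::read.tree(text = "((a:1,b:1)X:1,(c:1,d:1)Y:1)R;")
  tr <- label_nodes(tr)   # deterministic N labels
  # no switching: everyone inherits the root's binder state
  h0 <- simulate_binder_history(tr, cat_, switch_rate = 0, seed = 1)
  expect_true(all(h0$verdicts == "binder"))
  # force an abolishing substitution on one clade branch
  labs <- node_labels(tr)
  root_lab <- labs[length(tr$tip.label) + 1]
  ab <- match_node_by_leafset(tr, c("a", "b"))
  key <- paste0(root_lab, "->", labs[ab])
  forced <- setNames(list(c("3.37" = "A")), key)
  h1 <- simulate_binder_history(tr, cat_, switch_rate = 0, seed = 1,
                                forced = forced)
  expect_equal(unname(h1$verdicts[c("a", "b")]),
               c("non_binder", "non_binder"))
  expect_equal(unname(h1$verdicts[c("c", "d")]), c("binder", "binder"))
})

test_that("convergent gain shows up as different winning modes", {
  cat_ <- load_catalog()
  tr <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  tr <- label_nodes(tr)
  labs <- node_labels(tr)
  root_lab <- labs[length(tr$tip.label) + 1]
  ab <- labs[match_node_by_leafset(tr, c("a", "b"))]
  cd <- labs[match_node_by_leafset(tr, c("c", "d"))]
  forced <- list(residue_map("hT2R10"), residue_map("hT2R46"))
  names(forced) <- c(paste0(root_lab, "->", ab), paste0(root_lab, "->", cd))
  h <- simulate_binder_history(tr, cat_, switch_rate = 0, seed = 1,
                               root_profile = residue_map("N2"),
                               forced = forced)
  expect_equal(unname(h$verdicts[c("a", "b", "c", "d")]), rep("binder", 4))
  ra <- classify_binder(h$residues[["a"]], cat_)
  rc <- classify_binder(h$residues[["c"]], cat_)
  expect_equal(ra$mode_verdicts[["R10"]], "binder")
  expect_false(rc$mode_verdicts[["R10"]] == "binder")
  expect_equal(rc$mode_verdicts[["R46"]], "binder")
  # the root itself is not a binder in either mode
  expect_equal(unname(h$verdicts[[root_lab]]), "non_binder")
})
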