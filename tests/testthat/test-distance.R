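test_that("poisson distance matches its closed form", {
  m <- subst_model("poisson_equal")
  expect_equal(pairwise_distance("AAAA", "AAAA", m), 0)
  a <- paste(rep(c("A", "C"), 10), collapse = "")
  b <- paste(rep(c("A", "A"), 10), collapse = "")   # mismatch prop 0.5
  expect_equal(pairwise_distance(a, b, m), 0.70985, tolerance = 1e-5)
  expect_warning(d <- pairwise_distance(paste(rep("A", 20), collapse = ""),
                                        paste(rep("C", 20), collapse = ""),
                                        m), "saturation")
  expect_equal(d, 10)
})

test_that("ML distance under an equal-rate empirical model equals the formula", {
  # a PAML file with unit exchangeabilities and equal frequencies routes
  # through the 1-D ML optimizer; the answer must match the closed form
  f <- tempfile()
  rates <- unlist(lapply(1:19, function(i) rep(1, i)))
  writeLines(c(paste(rates, collapse = " "),
               paste(rep(0.05, 20), collapse = " ")), f)
  m <- subst_model("empirical", paml_file = f)
  set.seed(20)
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  a <- sample(aas, 400, replace = TRUE)
  b <- a
  idx <- sample(400, 80)
  b[idx] <- sample(aas, 80, replace = TRUE)
  p <- mean(a != b)
  d_ml <- pairwise_distance(paste(a, collapse = ""),
                            paste(b, collapse = ""), m)
  d_closed <- -(19 / 20) * log(1 - (20 / 19) * p)
  expect_equal(d_ml, d_closed, tolerance = 1e-6)
})

test_that("neighbor joining recovers additive and ultrametric matrices", {
  # additive matrix of ((a:1,b:2):1,(c:3,d:4))
  D <- matrix(c(0, 3, 5, 6,
                3, 0, 6, 7,
                5, 6, 0, 7,
                6, 7, 7, 0), 4, 4,
              dimnames = list(c("a", "b", "c", "d"), c("a", "b", "c", "d")))
  tr <- nj_tree(D)
  expect_equal(as.matrix(stats::cophenetic(tr))[rownames(D), colnames(D)],
               D, tolerance = 1e-10)
  truth <- ape::read.tree(text = "((a:1,b:2):1,(c:3,d:4):0);")
  expect_equal(ape::dist.topo(ape::unroot(truth), ape::unroot(tr)), 0,
               ignore_attr = TRUE)

  # 3 taxa: lengths solve the three-point formulas
  D3 <- matrix(c(0, 3, 5, 3, 0, 6, 5, 6, 0), 3, 3,
               dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  t3 <- nj_tree(D3)
  len <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(len[["a"]], (3 + 5 - 6) / 2)
  expect_equal(len[["b"]], (3 + 6 - 5) / 2)
  expect_equal(len[["c"]], (5 + 6 - 3) / 2)

  # ultrametric input reproduced exactly
  set.seed(6)
  tu <- ape::rcoal(6)
  Du <- as.matrix(stats::cophenetic(tu))
  expect_equal(as.matrix(stats::cophenetic(nj_tree(Du)))[rownames(Du),
                                                         colnames(Du)],
               Du, tolerance = 1e-10)

  Dbad <- D; Dbad[1, 2] <- 99
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("branch-length optimization attains the pairwise ML distance", {
  m <- subst_model("empirical")
  set.seed(21)
  tr2 <- ape::read.tree(text = "(a:0.05,b:0.05);")
  sim <- simulate_protein(sim_config(tr2, m, 800, seed = 5))
  opt <- optimize_branch_lengths(tr2, sim$msa, m)
  d <- pairwise_distance(sim$msa$seqs[["a"]], sim$msa$seqs[["b"]], m)
  expect_equal(sum(opt$edge.length), d, tolerance = 1e-4)
})

test_that("optimization is monotone and a fixed point at the optimum", {
  m <- subst_model("poisson_equal")
  tr <- scaled_coal(5, 0.4, seed = 30)
  sim <- simulate_protein(sim_config(tr, m, 300, seed = 31))
  start <- tr
  start$edge.length <- rep(0.2, nrow(tr$edge))
  ll0 <- log_likelihood(start, sim$msa, m)
  opt <- optimize_branch_lengths(start, sim$msa, m)
  expect_gte(attr(opt, "loglik"), ll0)
  reopt <- optimize_branch_lengths(opt, sim$msa, m, max_sweeps = 1)
  expect_lt(abs(attr(reopt, "loglik") - attr(opt, "loglik")), 1e-4)
})

test_that("branch lengths are recovered from long simulated alignments", {
  set.seed(42)
  tr <- ape::unroot(ape::rtree(8))
  tr$edge.length <- pmax(tr$edge.length * 0.2, 0.08)
  m <- subst_model("empirical")
  sim <- simulate_protein(sim_config(tr, m, 5000, seed = 2))
  start <- tr
  start$edge.length <- rep(0.1, nrow(tr$edge))
  opt <- optimize_branch_lengths(start, sim$msa, m)
  expect_lt(max(abs(opt$edge.length - tr$edge.length) / tr$edge.length),
            0.15)
})
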