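test_that("FASTA round trip is lossless and normalizes case", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">a", "acd"), f)
  s <- read_fasta(f)
  expect_equal(unname(s$seqs), "ACD")
  expect_equal(s$ids, "a")
  for (seed in 1:5) {
    x <- random_seqset(n = 4, len = 25, seed = seed)
    write_fasta(x, f)
    y <- read_fasta(f, aligned = TRUE)
    expect_identical(y$seqs, x$seqs)
  }
})

test_that("FASTA errors: duplicate ids named, empty file rejected", {
  f <- tempfile(fileext = ".fasta")
  writeLines(c(">dup", "ACD", ">dup", "ACE"), f)
  expect_error(read_fasta(f), "dup")
  writeLines(character(0), f)
  expect_error(read_fasta(f), "empty|parse|read", ignore.case = TRUE)
})

test_that("Newick round trip preserves topology, lengths, internal labels", {
  f <- tempfile(fileext = ".nwk")
  writeLines("(a:0.1,b:0.2);", f)
  tr <- read_newick(f)
  expect_equal(sort(tr$tip.label), c("a", "b"))
  expect_equal(sort(tr$edge.length), c(0.1, 0.2))

  writeLines("((a:1,b:1)N2:1,c:2);", f)
  tr <- read_newick(f)
  expect_true("N2" %in% tr$node.label)

  set.seed(4)
  t0 <- ape::rtree(10)
  write_newick(t0, f)
  t1 <- read_newick(f)
  expect_equal(ape::dist.topo(ape::unroot(t0), ape::unroot(t1)), 0,
               ignore_attr = TRUE)
  expect_equal(signif(sort(t1$edge.length), 10),
               signif(sort(t0$edge.length), 10))

  writeLines("(a:0.1,b:-0.2);", f)
  expect_error(read_newick(f), "negative")
})

test_that("BW labels anchor on the reference and follow it across gaps", {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(2)
  ref <- sample(aas, 300, replace = TRUE)
  ref[88] <- "W"; ref[239] <- "Y"; ref[263] <- "M"
  msa <- seq_set(c(hT2R10 = paste(ref, collapse = ""),
                   other = paste(sample(aas, 300, replace = TRUE),
                                 collapse = "")), aligned = TRUE)
  ann <- data.frame(position = c(88, 239, 263),
                    label = c("3.32", "6.51", "7.39"))
  bw <- map_bw_numbers(msa, "hT2R10", ann)
  # ungapped reference: column index = position - 1 (0-based)
  expect_equal(unname(bw$label_to_column[c("3.32", "6.51", "7.39")]),
               c(87, 238, 262))
  res <- extract_key_residues(msa, bw, c("3.32", "6.51", "7.39"))
  expect_equal(unlist(res["hT2R10", ]), c("3.32" = "W", "6.51" = "Y",
                                          "7.39" = "M"))

  # inserting gap columns elsewhere must not move the labels off W88
  gapped <- seq_set(c(hT2R10 = paste0("----", paste(ref, collapse = "")),
                      other = paste0("ACDE", paste(ref, collapse = ""))),
                    aligned = TRUE)
  bw2 <- map_bw_numbers(gapped, "hT2R10", ann)
  col <- bw2$label_to_column[["3.32"]] + 1
  expect_equal(substr(gapped$seqs[["hT2R10"]], col, col), "W")
  expect_equal(col, 88 + 4)

  expect_error(map_bw_numbers(msa, "hT2R10",
                              data.frame(position = 999, label = "9.99")),
               "outside")
  expect_error(map_bw_numbers(msa, "nope", ann), "reference")
})

test_that("hT2R46-style annotation resolves 7.43 to F269", {
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(3)
  ref <- sample(aas, 300, replace = TRUE)
  ref[241] <- "Y"; ref[269] <- "F"
  msa <- seq_set(c(hT2R46 = paste(ref, collapse = "")), aligned = TRUE)
  bw <- map_bw_numbers(msa, "hT2R46",
                       data.frame(position = c(241, 269),
                                  label = c("6.51", "7.43")))
  res <- extract_key_residues(msa, bw, c("6.51", "7.43"))
  expect_equal(unname(unlist(res["hT2R46", ])), c("Y", "F"))
})

test_that("homolog filtering applies identity and length rules", {
  a <- "ACDEFGHIKL"
  b <- "ASDYFGHVKP"   # 4 substitutions -> 60% identity
  expect_equal(pairwise_identity(a, b), 60)
  s <- seq_set(c(q = a, hit = b))
  kept <- filter_homologs(s, "q", min_identity_pct = 55, min_length = 5)
  expect_true("hit" %in% kept$ids)
  kept <- filter_homologs(s, "q", min_identity_pct = 65, min_length = 5)
  expect_false("hit" %in% kept$ids)
  expect_true("q" %in% kept$ids)      # query always retained
  expect_equal(pairwise_identity(a, a), 100)

  # fragments of exactly min_length residues are removed
  aas <- strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]]
  set.seed(5)
  q <- paste(sample(aas, 300, replace = TRUE), collapse = "")
  frag265 <- substr(q, 1, 265)
  frag266 <- substr(q, 1, 266)
  s2 <- seq_set(c(q = q, frag265 = frag265, frag266 = frag266))
  kept <- filter_homologs(s2, "q", 55, 265)
  expect_false("frag265" %in% kept$ids)
  expect_true("frag266" %in% kept$ids)

  # idempotence
  again <- filter_homologs(kept, "q", 55, 265)
  expect_identical(again$seqs, kept$seqs)
  expect_error(filter_homologs(s2, "missing"), "query")
})
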