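test_that("bundled catalog satisfies its structural invariants", {
  cat_ <- load_catalog()
  expect_equal(sum(cat_$mode == "R10"), 12)
  expect_equal(sum(cat_$mode == "R46"), 15)
  expect_equal(length(unique(cat_$label)), 20)
  expect_equal(sum(table(cat_$label) == 2), 7)
  # corruption guard
  raw <- jsonlite::fromJSON(system.file("extdata",
                                        "key_position_catalog.json",
                                        package = "bitterevo"),
                            simplifyDataFrame = FALSE)
  bad <- tempfile(fileext = ".json")
  jsonlite::write_json(raw[-1], bad, auto_unbox = TRUE)
  expect_error(load_catalog(bad), "invariants")
})

test_that("property classes and chemical similarity behave as documented", {
  p <- aa_properties(c("E", "K", "V", "W"))
  expect_equal(p$charge, c("negative", "positive", "neutral", "neutral"))
  expect_equal(p$hydropathy[3], "hydrophobic")
  expect_equal(p$volume, c("medium", "medium", "medium", "large"))
  expect_true(chemically_similar("V", "I"))
  expect_true(chemically_similar("M", "I"))
  expect_true(chemically_similar("T", "S"))
  expect_false(chemically_similar("Q", "H"))   # charge class differs
  expect_false(chemically_similar("L", "F"))   # volume class differs
  expect_false(chemically_similar("V", "T"))   # hydropathy differs
})

test_that("conserved counts reproduce the published worked examples", {
  cat_ <- load_catalog()
  n2 <- conserved_count(residue_map("N2"), cat_, "both")
  expect_equal(n2$n_conserved, 11)
  expect_equal(n2$n_total, 20)
  for (node in c("N94", "N93", "N83", "N82")) {
    cc <- conserved_count(residue_map(node), cat_, "R10")
    expect_equal(cc$n_conserved, 12)
    expect_equal(cc$n_total, 12)
  }
  self <- conserved_count(residue_map("hT2R10"), cat_, "R10")
  expect_equal(self$n_conserved, 12)
  n34 <- conserved_count(residue_map("N34"), cat_, "R46")
  expect_gte(n34$n_conserved, 14)
  # N24 differs from the R46 keys at exactly two chemically distinct sites
  n24 <- conserved_count(residue_map("N24"), cat_, "R46")
  expect_equal(n24$n_total - n24$n_conserved, 2)
  expect_true(all(!chemically_similar(n24$details$observed,
                                      n24$details$key)))
  expect_error(conserved_count(residue_map("N2")[-1], cat_, "both"),
               "lacks")
})

test_that("binder verdicts reproduce the published calls", {
  cat_ <- load_catalog()
  av <- read.table(system.file("extdata", "ancestor_verdicts.tsv",
                               package = "bitterevo"),
                   header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  for (i in seq_len(nrow(av))) {
    bc <- classify_binder(residue_map(av$id[i]), cat_)
    expect_equal(bc$verdict, av$expected_verdict[i],
                 label = paste("verdict for", av$id[i]))
  }
  sv <- load_species_variants()
  for (id in names(sv$residues)) {
    bc <- classify_binder(sv$residues[[id]], cat_)
    expect_equal(bc$verdict, unname(sv$expected[[id]]),
                 label = paste("verdict for", id))
  }
  # mode-level checks
  expect_equal(classify_binder(residue_map("hT2R46"),
                               cat_)$mode_verdicts[["R46"]], "binder")
  expect_equal(classify_binder(residue_map("hT2R10"),
                               cat_)$mode_verdicts[["R10"]], "binder")
})

test_that("verdicts are deterministic and abolishing changes never help", {
  cat_ <- load_catalog()
  base <- residue_map("hT2R46")
  v1 <- classify_binder(base, cat_)
  v2 <- classify_binder(base, cat_)
  expect_identical(v1$verdict, v2$verdict)
  expect_identical(v1$evidence, v2$evidence)
  order_ <- c(non_binder = 1, uncertain = 2, reduced_binder = 3, binder = 4)
  # every rule-listed abolishing substitution, applied to the matching
  # receptor background, must not improve the verdict
  for (i in seq_len(nrow(cat_))) {
    for (r in cat_$rules[[i]]) {
      if (is.null(r$residues) || r$effect != "abolished") next
      bg <- residue_map(if (cat_$mode[i] == "R10") "hT2R10" else "hT2R46")
      before <- classify_binder(bg, cat_)$verdict
      for (sub in strsplit(r$residues, "")[[1]]) {
        mut <- bg
        mut[[cat_$label[i]]] <- sub
        after <- classify_binder(mut, cat_)$verdict
        expect_lte(order_[[after]], order_[[before]])
      }
    }
  }
})

test_that("dual predictions are judged on the primary residue", {
  cat_ <- load_catalog()
  n34 <- residue_map("N34")
  expect_equal(n34[["7.42"]], "T/A")
  bc <- classify_binder(n34, cat_)
  ev <- bc$evidence
  expect_equal(ev$observed[ev$mode == "R46" & ev$bw_label == "7.42"], "T")
  expect_equal(bc$verdict, "reduced_binder")
})
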