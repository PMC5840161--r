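#' Run the full analysis pipeline
#'
#' Orchestrates filtering, tree building (or a user tree), ancestral
#' reconstruction, relative dating, binder classification and, when a codon
#' alignment is supplied, site-specific selection analysis. Every output is
#' a plain TSV/FASTA/Newick file re-readable by the package's own readers;
#' outputs of a stage are written to `<name>.partial` and renamed on stage
#' completion, so an aborted run leaves `.partial` files behind.
#'
#' @param config A named list or the path to a YAML/JSON configuration with
#'   fields: `protein_fasta` (aligned, required), `codon_fasta` (optional),
#'   `newick` (optional; built by neighbor joining when absent),
#'   `bw_annotation` (TSV path, required for key-residue and binder stages),
#'   `reference_id`, `query_id`, `outgroup_ids`, `catalog` (optional path),
#'   `min_identity_pct` (default 55), `min_length` (default 265), `alpha`
#'   (0.05), `tie_delta` (0.05), `model` (`"empirical"` or
#'   `"poisson_equal"`), `gamma_shape` (optional), `seed` (1),
#'   `optimize_branch_lengths` (FALSE), `output_dir` (required).
#' @return Invisibly, a list of output file paths plus the fitted objects
#'   (`tree`, `profile`, `reltime`, `calls`, `selection`).
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config)) yaml::read_yaml(config)
              else jsonlite::fromJSON(config)
  }
  defaults <- list(min_identity_pct = 55, min_length = 265, alpha = 0.05,
                   tie_delta = 0.05, model = "empirical",
                   gamma_shape = NULL, seed = 1L,
                   optimize_branch_lengths = FALSE)
  config <- modifyList(defaults, config)
  for (f in c("protein_fasta", "output_dir"))
    if (is.null(config[[f]])) stop("config field required: ", f)
  out <- config$output_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(config$seed))
  paths <- list()
  log_lines <- c(sprintf("bitterevo %s | R %s.%s",
                         as.character(utils::packageVersion("bitterevo")),
                         R.version$major, R.version$minor),
                 sprintf("seed: %d", as.integer(config$seed)))
  cfg_json <- tempfile(fileext = ".json")
  jsonlite::write_json(config, cfg_json, auto_unbox = TRUE, null = "null")
  log_lines <- c(log_lines,
                 sprintf("config_hash: %s", unname(tools::md5sum(cfg_json))))
  stage <- function(name, expr) {
    t0 <- Sys.time()
    res <- tryCatch(expr, error = function(e)
      stop(sprintf("pipeline stage '%s' failed: %s", name,
                   conditionMessage(e)), call. = FALSE))
    log_lines <<- c(log_lines, sprintf("stage %s: %.2fs", name,
                                       as.numeric(Sys.time() - t0,
                                                  units = "secs")))
    res
  }
  emit <- function(final, writer) {
    partial <- paste0(final, ".partial")
    writer(partial)
    file.rename(partial, final)
    final
  }
  model <- subst_model(config$model, gamma_shape = config$gamma_shape)

  ## (a) filtered sequence set
  msa <- stage("filter", {
    msa <- read_fasta(config$protein_fasta, alphabet = "protein",
                      aligned = TRUE)
    if (!is.null(config$query_id))
      msa <- filter_homologs(msa, config$query_id,
                             config$min_identity_pct, config$min_length)
    msa
  })
  paths$filtered_fasta <- emit(file.path(out, "filtered.fasta"),
                               function(p) write_fasta(msa, p))

  ## (b) rooted, labeled tree
  tree <- stage("tree", {
    tr <- if (!is.null(config$newick)) read_newick(config$newick)
          else nj_tree(distance_matrix(msa, model))
    tr <- ape::keep.tip(tr, intersect(tr$tip.label, msa$ids))
    if (!is.null(config$outgroup_ids))
      tr <- ape::root(tr, outgroup = intersect(config$outgroup_ids,
                                               tr$tip.label),
                      resolve.root = TRUE)
    if (isTRUE(config$optimize_branch_lengths))
      tr <- optimize_branch_lengths(tr, msa, model)
    label_nodes(tr)
  })
  paths$tree <- emit(file.path(out, "tree.nwk"),
                     function(p) write_newick(tree, p))

  ## (c) ancestral reconstruction + key-residue matrix
  profile <- stage("asr", marginal_asr(tree, msa, model))
  calls <- NULL
  bwmap <- NULL
  if (!is.null(config$bw_annotation)) {
    ann <- read_bw_annotation(config$bw_annotation)
    ref <- config$reference_id %||% config$query_id
    bwmap <- map_bw_numbers(msa, ref, ann)
    keys <- stage("key_residues", {
      ex <- extract_key_residues(msa, bwmap, ann$label)
      anc <- extract_key_residues(profile, bwmap, ann$label,
                                  tie_delta = config$tie_delta)
      pp <- rbind(matrix(NA_real_, nrow(ex), ncol(ex),
                         dimnames = dimnames(ex)),
                  attr(anc, "posterior"))
      both <- rbind(ex, anc)
      attr(both, "posterior") <- pp
      both
    })
    paths$key_residues <- emit(file.path(out, "key_residues.tsv"),
                               function(p) write_key_matrix(keys, p))

    ## (d) binder calls (needs the catalog positions covered)
    catalog <- load_catalog(config$catalog)
    if (all(unique(catalog$label) %in% ann$label)) {
      calls <- stage("classify", {
        entities <- rownames(keys)
        do.call(rbind, lapply(entities, function(id) {
          res <- setNames(unlist(keys[id, ]), colnames(keys))
          bc <- classify_binder(res, catalog)
          data.frame(id = id, verdict = bc$verdict,
                     r10_verdict = bc$mode_verdicts[["R10"]],
                     r46_verdict = bc$mode_verdicts[["R46"]],
                     mismatches = sum(bc$evidence$effect != "match"),
                     stringsAsFactors = FALSE)
        }))
      })
      paths$binder_calls <- emit(file.path(out, "binder_calls.tsv"),
        function(p) write.table(calls, p, sep = "\t", quote = FALSE,
                                row.names = FALSE))
    } else {
      log_lines <- c(log_lines,
                     "stage classify: skipped (annotation does not cover catalog)")
    }
  }

  ## (e) relative times
  rt <- stage("reltime", relative_rates(tree))
  paths$reltime <- emit(file.path(out, "reltime.tsv"),
                        function(p) write_reltime(rt, p))

  ## (f) site-specific selection
  sel <- NULL
  if (!is.null(config$codon_fasta)) {
    sel <- stage("dnds", {
      cmsa <- read_fasta(config$codon_fasta, alphabet = "dna",
                         aligned = TRUE)
      tr2 <- ape::keep.tip(tree, intersect(tree$tip.label, cmsa$ids))
      tab <- site_dnds(cmsa, tr2, alpha = config$alpha)
      if (!is.null(bwmap)) tab <- join_bw_labels(tab, bwmap)
      tab
    })
    paths$selection <- emit(file.path(out, "selection.tsv"),
      function(p) write.table(sel, p, sep = "\t", quote = FALSE,
                              row.names = FALSE))
  }

  ## (g) run log
  paths$log <- emit(file.path(out, "run_log.txt"),
                    function(p) writeLines(log_lines, p))
  invisible(c(paths, list(tree = tree, profile = profile, reltime = rt,
                          calls = calls, selection = sel)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
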