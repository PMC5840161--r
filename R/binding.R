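## Key-position catalog and the strychnine binder-call rule engine.
##
## The catalog records, for each Ballesteros-Weinstein position known from
## site-directed mutagenesis to matter for strychnine response in one of the
## two human receptor binding modes (T2R10-like, T2R46-like), the key
## residue, whether the position is critical (loss-of-function mutations
## reported) or supporting, and ordered substitution-effect rules. The
## engine scores a residue map against each mode and returns the better
## verdict: binder > reduced_binder > uncertain > non_binder.

VERDICT_LEVELS <- c("non_binder", "uncertain", "reduced_binder", "binder")

# Kyte-Doolittle hydropathy
KD_HYDROPATHY <- c(A = 1.8, R = -4.5, N = -3.5, D = -3.5, C = 2.5, Q = -3.5,
                   E = -3.5, G = -0.4, H = -3.2, I = 4.5, L = 3.8, K = -3.9,
                   M = 1.9, F = 2.8, P = -1.6, S = -0.8, T = -0.7, W = -0.9,
                   Y = -1.3, V = 4.2)
# Zamyatnin side-chain volumes (A^3)
AA_VOLUME <- c(A = 88.6, R = 173.4, N = 114.1, D = 111.1, C = 108.5,
               Q = 143.8, E = 138.4, G = 60.1, H = 153.2, I = 166.7,
               L = 166.7, K = 168.6, M = 162.9, F = 189.9, P = 112.7,
               S = 89.0, T = 116.1, W = 227.8, Y = 193.6, V = 140.0)

#' Amino-acid property classes used by the rule engine
#'
#' Charge: negative `{D,E}`, positive `{K,R,H}`, else neutral. Hydropathy:
#' hydrophobic when the Kyte-Doolittle index is above 0. Volume: small
#' (<= 117 A^3), medium (<= 170), large (> 170), on Zamyatnin side-chain
#' volumes.
#'
#' @param aa Single-letter amino acid(s).
#' @return `aa_properties()`: data frame with `charge`, `hydropathy`,
#'   `volume` classes.
#' @export
#' @examples
#' aa_properties(c("E", "K", "V"))
aa_properties <- function(aa) {
  aa <- toupper(aa)
  charge <- ifelse(aa %in% c("D", "E"), "negative",
                   ifelse(aa %in% c("K", "R", "H"), "positive", "neutral"))
  hydro <- ifelse(KD_HYDROPATHY[aa] > 0, "hydrophobic", "hydrophilic")
  vol <- cut(AA_VOLUME[aa], c(0, 117, 170, Inf),
             labels = c("small", "medium", "large"))
  data.frame(aa = aa, charge = charge, hydropathy = unname(hydro),
             volume = as.character(vol), stringsAsFactors = FALSE)
}

#' @rdname aa_properties
#' @param a,b Single-letter amino acids.
#' @return `chemically_similar()`: `TRUE` when the two residues share
#'   charge class, hydropathy class and volume class.
#' @export
chemically_similar <- function(a, b) {
  pa <- aa_properties(a); pb <- aa_properties(b)
  pa$charge == pb$charge & pa$hydropathy == pb$hydropathy &
    pa$volume == pb$volume
}

#' Load the key-position catalog
#'
#' Reads the bundled (or a user-supplied) JSON catalog of key strychnine-
#' binding positions and substitution-effect rules, and verifies its
#' structural invariants: 12 T2R10-mode entries, 15 T2R46-mode entries,
#' 20 distinct positions in the union, 7 positions carrying both modes.
#'
#' @param path Path to a catalog JSON; default is the bundled catalog.
#' @return A `key_position_catalog`: data frame with columns `label`,
#'   `mode`, `key_residue`, `criticality` and a list-column `rules`.
#' @export
load_catalog <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "key_position_catalog.json",
                        package = "bitterevo")
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  entries <- lapply(raw, function(e) {
    data.frame(label = e$label, mode = e$mode, key_residue = e$key_residue,
               criticality = e$criticality, stringsAsFactors = FALSE)
  })
  df <- do.call(rbind, entries)
  df$rules <- lapply(raw, function(e) e$rules)
  n10 <- sum(df$mode == "R10"); n46 <- sum(df$mode == "R46")
  nun <- length(unique(df$label))
  nshared <- sum(table(df$label) == 2)
  if (n10 != 12 || n46 != 15 || nun != 20 || nshared != 7)
    stop(sprintf(paste("catalog fails invariants (got %d R10, %d R46,",
                       "%d distinct, %d shared; need 12/15/20/7) -",
                       "fixture corrupted?"), n10, n46, nun, nshared))
  class(df) <- c("key_position_catalog", "data.frame")
  df
}

# effect of observing `obs` where `key` is expected, under ordered rules.
# Returns one of tolerated/reduced/abolished/similar/disruptive.
substitution_effect <- function(obs, key, rules) {
  if (obs == key) return("match")
  if (!obs %in% names(KD_HYDROPATHY)) return("disruptive")
  for (r in rules) {
    hit <- if (!is.null(r$residues)) {
      obs %in% strsplit(r$residues, "")[[1]]
    } else if (!is.null(r$property)) {
      p <- aa_properties(obs)
      switch(r$property,
             hydrophobic = p$hydropathy == "hydrophobic",
             hydrophilic = p$hydropathy == "hydrophilic",
             positive = p$charge == "positive",
             negative = p$charge == "negative",
             large = p$volume == "large",
             small = p$volume == "small",
             FALSE)
    } else FALSE
    if (hit) return(r$effect)
  }
  if (chemically_similar(obs, key)) "similar" else "disruptive"
}

# first token of a possibly dual "T/A" prediction
primary_residue <- function(x) sub("/.*$", "", x)

#' Count conserved key positions
#'
#' How many catalog positions carry their key residue in a residue map.
#' With `mode = "both"` the 20 distinct positions are counted, a position
#' being conserved when the observed residue equals the key residue of
#' *either* mode keyed there. Dual predictions (`"T/A"`) are judged on the
#' primary (first) residue.
#'
#' @param residues Named character vector: BW label -> residue.
#' @param catalog A [load_catalog()] result.
#' @param mode `"both"`, `"R10"`, or `"R46"`.
#' @return List with `n_conserved`, `n_total`, and `details` (data frame of
#'   mismatching positions).
#' @export
conserved_count <- function(residues, catalog, mode = c("both", "R10", "R46")) {
  mode <- match.arg(mode)
  cat_sub <- if (mode == "both") catalog else catalog[catalog$mode == mode, ]
  labels <- unique(cat_sub$label)
  missing <- setdiff(labels, names(residues))
  if (length(missing))
    stop("residue map lacks catalog position(s): ",
         paste(missing, collapse = ", "))
  conserved <- vapply(labels, function(l) {
    keys <- cat_sub$key_residue[cat_sub$label == l]
    primary_residue(residues[[l]]) %in% keys
  }, logical(1))
  details <- data.frame(label = labels[!conserved],
                        observed = unname(residues[labels[!conserved]]),
                        key = vapply(labels[!conserved], function(l)
                          paste(cat_sub$key_residue[cat_sub$label == l],
                                collapse = "/"), character(1)),
                        stringsAsFactors = FALSE)
  list(n_conserved = sum(conserved), n_total = length(labels),
       details = details)
}

# verdict for one mode
mode_verdict <- function(residues, catalog, mode) {
  cat_sub <- catalog[catalog$mode == mode, ]
  missing <- setdiff(cat_sub$label, names(residues))
  if (length(missing))
    stop("residue map lacks catalog position(s): ",
         paste(missing, collapse = ", "))
  ev <- lapply(seq_len(nrow(cat_sub)), function(i) {
    obs <- primary_residue(residues[[cat_sub$label[i]]])
    data.frame(bw_label = cat_sub$label[i], observed = obs,
               key = cat_sub$key_residue[i],
               criticality = cat_sub$criticality[i],
               effect = substitution_effect(obs, cat_sub$key_residue[i],
                                            cat_sub$rules[[i]]),
               stringsAsFactors = FALSE)
  })
  ev <- do.call(rbind, ev)
  mm <- ev[ev$effect != "match", ]
  verdict <- if (nrow(mm) == 0) {
    "binder"
  } else if (any(mm$effect == "abolished")) {
    "non_binder"
  } else if (any(mm$effect == "disruptive" & mm$criticality == "critical") ||
             sum(mm$effect == "disruptive") >= 2) {
    "non_binder"
  } else if (any(mm$effect %in% c("disruptive", "similar"))) {
    "uncertain"
  } else {
    "reduced_binder"
  }
  list(verdict = verdict, evidence = ev)
}

#' Classify a sequence as a strychnine binder
#'
#' Scores a residue map (BW label -> residue, covering all 20 catalog
#' positions) against both binding modes and returns the better verdict.
#' Per mode: all key residues present gives `binder`; any rule-listed
#' abolishing substitution gives `non_binder`; a non-conservative
#' substitution at a critical position, or two or more non-conservative
#' substitutions, give `non_binder`; otherwise unknown-effect substitutions
#' (including chemically similar ones, whose effect mutagenesis has not
#' resolved) give `uncertain`; and substitutions that are all tolerated or
#' sensitivity-reducing give `reduced_binder`.
#'
#' @param residues Named character vector: BW label -> residue (dual
#'   predictions `"T/A"` are judged on the primary residue).
#' @param catalog A [load_catalog()] result.
#' @return A `binder_call`: list with `verdict`, `mode_verdicts` (named,
#'   R10/R46), and `evidence` (per-position data frame for both modes).
#' @export
classify_binder <- function(residues, catalog) {
  stopifnot(inherits(catalog, "key_position_catalog"))
  r10 <- mode_verdict(residues, catalog, "R10")
  r46 <- mode_verdict(residues, catalog, "R46")
  mv <- c(R10 = r10$verdict, R46 = r46$verdict)
  best <- VERDICT_LEVELS[max(match(mv, VERDICT_LEVELS))]
  ev <- rbind(cbind(mode = "R10", r10$evidence),
              cbind(mode = "R46", r46$evidence))
  structure(list(verdict = best, mode_verdicts = mv, evidence = ev),
            class = "binder_call")
}

#' @export
print.binder_call <- function(x, ...) {
  cat(sprintf("binder_call: %s (R10: %s, R46: %s)\n", x$verdict,
              x$mode_verdicts[["R10"]], x$mode_verdicts[["R46"]]))
  mm <- x$evidence[x$evidence$effect != "match", ]
  if (nrow(mm))
    print(mm, row.names = FALSE)
  invisible(x)
}

#' Bundled key-residue matrices
#'
#' `load_reference_residues()` reads the bundled matrix of residues at the
#' 20 key positions for the two human receptors and the reconstructed
#' ancestors discussed in the source studies (columns) by BW label (rows).
#' `load_species_variants()` reads the bundled per-species variant table
#' (key-residue differences relative to a base receptor) together with the
#' published binder verdicts, and expands each species to a full residue
#' map.
#'
#' @param path Optional path overriding the bundled file.
#' @return `load_reference_residues()`: data frame, rows = BW labels,
#'   columns = receptors/ancestors. `load_species_variants()`: list of
#'   `residues` (named list of residue maps) and `expected` (named verdict
#'   vector).
#' @export
load_reference_residues <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "key_residue_matrix.tsv",
                        package = "bitterevo")
  df <- read.table(path, header = TRUE, sep = "\t", check.names = FALSE,
                   stringsAsFactors = FALSE)
  rownames(df) <- df$bw_label
  df$bw_label <- NULL
  df
}

#' @rdname load_reference_residues
#' @export
load_species_variants <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "species_key_variants.tsv",
                        package = "bitterevo")
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE, na.strings = "")
  ref <- load_reference_residues()
  maps <- lapply(seq_len(nrow(df)), function(i) {
    base <- setNames(ref[[df$base[i]]], rownames(ref))
    if (!is.na(df$variants[i]) && nzchar(df$variants[i])) {
      for (v in strsplit(df$variants[i], ";")[[1]]) {
        kv <- strsplit(v, "=")[[1]]
        base[[kv[1]]] <- kv[2]
      }
    }
    base
  })
  names(maps) <- df$id
  list(residues = maps, expected = setNames(df$expected_verdict, df$id))
}

#' Extract one column of the reference matrix as a residue map
#'
#' @param column Column name (e.g. `"N2"`, `"hT2R10"`).
#' @param matrix_df Result of [load_reference_residues()].
#' @return Named character vector: BW label -> residue.
#' @export
residue_map <- function(column, matrix_df = load_reference_residues()) {
  if (!column %in% names(matrix_df))
    stop("no column '", column, "' in residue matrix")
  setNames(matrix_df[[column]], rownames(matrix_df))
}
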