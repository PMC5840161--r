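#' Anchor Ballesteros-Weinstein labels onto alignment columns
#'
#' Class A GPCR residues are compared across receptors through
#' Ballesteros-Weinstein (BW) indices (`X.50` is the most conserved residue
#' of transmembrane helix `X`); loop residues carry plain loop labels such
#' as `"ECL2"`. Given an annotation of the *ungapped* reference sequence
#' (1-based position -> label), this maps each annotated reference residue
#' to the alignment column that holds it, so that every sequence and
#' reconstructed ancestor can be read out at the same structural positions.
#'
#' @param msa Aligned [seq_set()] containing the reference.
#' @param reference_id Id of the reference sequence in `msa`.
#' @param annotation Data frame with columns `position` (1-based ungapped
#'   reference position) and `label` (BW or loop label), or a 2-column
#'   matrix-like object coercible to it.
#' @return A `bw_map`: list with `reference_id`, `column_to_label` (named
#'   character; names are 0-based column indices), `label_to_column`
#'   (named integer, 0-based).
#' @export
#' @examples
#' msa <- seq_set(c(ref = "AW-C", oth = "AWDC"), aligned = TRUE)
#' bw <- map_bw_numbers(msa, "ref", data.frame(position = 2, label = "3.32"))
#' bw$label_to_column[["3.32"]]  # column 1 (0-based)
map_bw_numbers <- function(msa, reference_id, annotation) {
  stopifnot(inherits(msa, "seq_set"), msa$aligned)
  if (!reference_id %in% msa$ids)
    stop("reference id not in alignment: ", reference_id)
  annotation <- as.data.frame(annotation)
  if (!all(c("position", "label") %in% names(annotation)))
    names(annotation)[1:2] <- c("position", "label")
  pos <- as.integer(annotation$position)
  lab <- as.character(annotation$label)
  if (anyDuplicated(lab))
    stop("duplicate BW label(s) in annotation: ",
         paste(unique(lab[duplicated(lab)]), collapse = ", "))
  refchars <- strsplit(msa$seqs[[reference_id]], "", fixed = TRUE)[[1]]
  ungapped_cols <- which(refchars != "-")     # 1-based MSA columns
  nref <- length(ungapped_cols)
  if (any(pos < 1L | pos > nref))
    stop("annotation position(s) outside ungapped reference length (",
         nref, "): ", paste(pos[pos < 1L | pos > nref], collapse = ", "))
  cols0 <- ungapped_cols[pos] - 1L            # 0-based internally
  structure(list(reference_id = reference_id,
                 column_to_label = setNames(lab, as.character(cols0)),
                 label_to_column = setNames(cols0, lab)),
            class = "bw_map")
}

#' @export
print.bw_map <- function(x, ...) {
  cat(sprintf("bw_map: %d labels anchored on '%s'\n",
              length(x$label_to_column), x$reference_id))
  invisible(x)
}

#' Resolve BW labels to 0-based alignment columns
#'
#' @param bwmap A `bw_map`.
#' @param labels Character vector of labels.
#' @return Integer vector of 0-based columns.
#' @export
bw_columns <- function(bwmap, labels) {
  stopifnot(inherits(bwmap, "bw_map"))
  missing <- setdiff(labels, names(bwmap$label_to_column))
  if (length(missing))
    stop("label(s) not in BW map: ", paste(missing, collapse = ", "))
  bwmap$label_to_column[labels]
}

#' Read a BW annotation table
#'
#' Two-column TSV: `position` (1-based ungapped reference position) and
#' `label`.
#'
#' @param path File path.
#' @return Data frame with columns `position`, `label`.
#' @export
read_bw_annotation <- function(path) {
  df <- read.table(path, header = TRUE, sep = "\t",
                   stringsAsFactors = FALSE)
  if (!all(c("position", "label") %in% names(df)))
    stop("annotation must have columns 'position' and 'label'")
  df$position <- as.integer(df$position)
  df$label <- as.character(df$label)
  df
}
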