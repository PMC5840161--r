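#' Pairwise percent identity by global alignment
#'
#' Identity between two (ungapped) sequences is computed on a global
#' (Needleman-Wunsch) alignment as matches divided by aligned columns,
#' excluding columns gapped in both sequences (none arise in a pairwise
#' alignment). The scoring scheme is fixed: BLOSUM62, gap opening 10,
#' gap extension 0.5.
#'
#' @param a,b Sequences (character scalars, protein).
#' @return Percent identity in `[0, 100]`.
#' @export
#' @examples
#' pairwise_identity("ACDEFGHIKL", "ACDEFGHIKV")  # 90
pairwise_identity <- function(a, b) {
  a <- gsub("-", "", toupper(a), fixed = TRUE)
  b <- gsub("-", "", toupper(b), fixed = TRUE)
  # BLOSUM62 has no 'X' rows in some releases; map unknowns to a neutral char
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::AAString(a), Biostrings::AAString(b),
    substitutionMatrix = "BLOSUM62", gapOpening = 10, gapExtension = 0.5,
    type = "global")
  s1 <- strsplit(as.character(Biostrings::alignedPattern(pa)), "")[[1]]
  s2 <- strsplit(as.character(Biostrings::alignedSubject(pa)), "")[[1]]
  keep <- !(s1 == "-" & s2 == "-")
  100 * sum(s1[keep] == s2[keep]) / sum(keep)
}

#' Filter homologous sequences by identity and length
#'
#' Mirrors the retrieval filter used to assemble receptor reference sets:
#' keep sequences with percent identity to the query at or above
#' `min_identity_pct` (global alignment, see [pairwise_identity()]) and
#' ungapped length strictly greater than `min_length` (fragments of
#' `min_length` residues or fewer are removed to avoid excessive gap opening
#' in ancestral reconstruction). The query is always retained. The operation
#' is idempotent.
#'
#' @param seqs A [seq_set()] (aligned or not; identity is computed on
#'   degapped sequences).
#' @param query_id Id of the query sequence.
#' @param min_identity_pct Identity threshold in percent (default 55).
#' @param min_length Length cutoff; sequences with ungapped length
#'   `<= min_length` are removed (default 265).
#' @return A `seq_set` with the retained records (original order).
#' @export
filter_homologs <- function(seqs, query_id, min_identity_pct = 55,
                            min_length = 265) {
  stopifnot(inherits(seqs, "seq_set"))
  if (!query_id %in% seqs$ids)
    stop("query id not in sequence set: ", query_id)
  q <- ungapped(seqs, query_id)
  keep <- vapply(seqs$ids, function(id) {
    if (id == query_id) return(TRUE)
    s <- ungapped(seqs, id)
    nchar(s) > min_length && pairwise_identity(q, s) >= min_identity_pct
  }, logical(1))
  subset_seqs(seqs, seqs$ids[keep])
}
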