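#' Construct a sequence set
#'
#' Container for a set of protein or DNA sequences, optionally aligned.
#' Sequences are stored upper-case. The protein alphabet is the 20 standard
#' amino acids plus gap `-` and unknown `X`; the DNA alphabet is `ACGT` plus
#' gap and `N`.
#'
#' @param seqs Named character vector of sequences (names are record ids).
#' @param aligned Logical; if `TRUE` all sequences must have equal length.
#' @param alphabet `"protein"` or `"dna"`.
#' @return An object of class `seq_set` with fields `ids`, `seqs`,
#'   `aligned`, `alphabet`.
#' @export
#' @examples
#' s <- seq_set(c(a = "ACDEF", b = "ACD-F"), aligned = TRUE)
#' nseq(s)
seq_set <- function(seqs, aligned = FALSE, alphabet = c("protein", "dna")) {
  alphabet <- match.arg(alphabet)
  if (is.null(names(seqs)) || any(!nzchar(names(seqs))))
    stop("all sequences must be named")
  ids <- names(seqs)
  if (anyDuplicated(ids))
    stop("duplicate sequence id(s): ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- toupper(as.character(seqs))
  names(seqs) <- ids
  if (aligned && length(unique(nchar(seqs))) > 1L)
    stop("aligned sequence set has unequal sequence lengths")
  ok <- if (alphabet == "protein") {
    paste0(AA_STATES, collapse = "")
  } else {
    paste0(NT_STATES, collapse = "")
  }
  extra <- if (alphabet == "protein") "X-" else "N-"  # '-' last: no range
  bad <- grepl(sprintf("[^%s%s]", ok, extra), seqs)
  if (any(bad))
    stop("invalid characters in sequence(s): ",
         paste(ids[bad], collapse = ", "))
  structure(list(ids = ids, seqs = seqs, aligned = aligned,
                 alphabet = alphabet),
            class = "seq_set")
}

#' @rdname seq_set
#' @param x A `seq_set`.
#' @export
nseq <- function(x) length(x$ids)

#' @export
print.seq_set <- function(x, ...) {
  cat(sprintf("seq_set: %d %s sequence(s)%s\n", nseq(x), x$alphabet,
              if (x$aligned) sprintf(", aligned (%d columns)",
                                     nchar(x$seqs[1])) else ""))
  invisible(x)
}

#' Subset a sequence set by id
#'
#' @param x A `seq_set`.
#' @param ids Character vector of record ids to keep (order preserved).
#' @return A `seq_set` with the selected records.
#' @export
subset_seqs <- function(x, ids) {
  missing <- setdiff(ids, x$ids)
  if (length(missing))
    stop("id(s) not in sequence set: ", paste(missing, collapse = ", "))
  seq_set(x$seqs[ids], aligned = x$aligned, alphabet = x$alphabet)
}

#' Read and write FASTA files
#'
#' Thin wrappers around [Biostrings::readBStringSet()] /
#' [Biostrings::writeXStringSet()] that return/accept [seq_set()] objects.
#' Input is normalized to upper case; duplicate ids and empty files are
#' errors. Writing then reading a set returns identical records.
#'
#' @param path File path.
#' @param alphabet `"protein"` or `"dna"`.
#' @param aligned Mark the returned set as aligned (lengths are checked).
#' @return `read_fasta()`: a `seq_set`.
#' @export
read_fasta <- function(path, alphabet = c("protein", "dna"),
                       aligned = FALSE) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("empty FASTA file: ", path)
  # keep only the first whitespace-delimited token of each header
  ids <- sub("\\s.*$", "", names(ss))
  seqs <- setNames(as.character(ss), ids)
  seq_set(seqs, aligned = aligned, alphabet = alphabet)
}

#' @rdname read_fasta
#' @param seqset A `seq_set` to write.
#' @return `write_fasta()`: the path, invisibly.
#' @export
write_fasta <- function(seqset, path) {
  stopifnot(inherits(seqset, "seq_set"))
  ss <- Biostrings::BStringSet(seqset$seqs)
  Biostrings::writeXStringSet(ss, path, width = 70L)
  invisible(path)
}

# character matrix (rows = sequences) from an aligned seq_set
seq_matrix <- function(seqset) {
  stopifnot(seqset$aligned)
  m <- do.call(rbind, strsplit(seqset$seqs, "", fixed = TRUE))
  rownames(m) <- seqset$ids
  m
}

# degapped sequence of one record
ungapped <- function(seqset, id) {
  gsub("-", "", seqset$seqs[[id]], fixed = TRUE)
}
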