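ALN_ALPHABET <- c("A", "C", "G", "T", "-", "N")

#' Construct a validated aligned sequence set
#'
#' @param seqs Named character vector of equal-length gapped sequences over
#'   `A/C/G/T/-/N` (lowercase accepted, upcased).
#' @param parent_id Name of the parent (reference) sequence, or `NULL` for
#'   alignments without a designated parent (e.g. haplotype alignments).
#' @param species Optional named character vector mapping sequence names to
#'   species labels.
#' @return Object of class `aligned_set`.
#' @export
aligned_set <- function(seqs, parent_id = NULL, species = NULL) {
  stopifnot(is.character(seqs), length(seqs) >= 1L, !is.null(names(seqs)))
  seqs <- toupper(seqs)
  w <- nchar(seqs)
  if (length(unique(w)) != 1L) stop("ragged alignment: unequal sequence lengths")
  bad <- grepl("[^ACGTN-]", seqs)
  if (any(bad)) {
    stop("unknown characters in sequences: ",
         paste(names(seqs)[bad], collapse = ", "))
  }
  if (!is.null(parent_id) && !parent_id %in% names(seqs)) {
    stop("parent sequence '", parent_id, "' not in alignment")
  }
  structure(list(seqs = seqs, parent_id = parent_id, species = species),
            class = "aligned_set")
}

#' Read a multi-FASTA alignment
#'
#' @param path FASTA file of equal-length gapped sequences.
#' @param parent_id Name of the parent sequence (must be present), or `NULL`.
#' @param species Optional named character vector of species labels.
#' @return An `aligned_set`.
#' @export
read_alignment <- function(path, parent_id = NULL, species = NULL) {
  x <- Biostrings::readBStringSet(path)
  if (length(x) < 2L) stop("alignment must contain >= 2 sequences")
  seqs <- as.character(x)
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  aligned_set(seqs, parent_id = parent_id, species = species)
}

#' Write an aligned set to FASTA
#'
#' @param aln An `aligned_set`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_alignment <- function(aln, path) {
  stopifnot(inherits(aln, "aligned_set"))
  Biostrings::writeXStringSet(Biostrings::BStringSet(aln$seqs), path)
  invisible(path)
}

#' @export
print.aligned_set <- function(x, ...) {
  cat("aligned_set:", length(x$seqs), "sequences x", nchar(x$seqs[1]),
      "columns")
  if (!is.null(x$parent_id)) cat(", parent =", x$parent_id)
  cat("\n")
  invisible(x)
}

ungap <- function(s) gsub("-", "", s, fixed = TRUE)
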