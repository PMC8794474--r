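# Per-base depth text: contig <TAB> 1-based position <TAB> depth, the format
# produced by `samtools depth`. Positions with zero depth may be omitted.

#' Write a depth track to three-column text
#'
#' @param track Named list of integer depth vectors (one per contig).
#' @param path Output path.
#' @param omit_zero Drop zero-depth positions (as `samtools depth` does
#'   without `-a`)?
#' @return `path`, invisibly.
#' @export
write_depth <- function(track, path, omit_zero = TRUE) {
  stopifnot(is.list(track), !is.null(names(track)))
  con <- file(path, "w")
  on.exit(close(con))
  for (ctg in names(track)) {
    d <- track[[ctg]]
    pos <- seq_along(d)
    if (omit_zero) {
      keep <- d > 0
      pos <- pos[keep]
      d <- d[keep]
    }
    if (length(pos)) {
      write.table(data.frame(ctg, pos, d), con, sep = "\t", quote = FALSE,
                  row.names = FALSE, col.names = FALSE)
    }
  }
  invisible(path)
}

#' Load a per-base depth track
#'
#' Reads three-column depth text (contig, 1-based position, depth). Positions
#' absent from the file are filled with depth 0 up to each contig's declared
#' length.
#'
#' @param path Input path.
#' @param lengths Named integer vector of contig lengths. Contigs in `lengths`
#'   absent from the file become all-zero tracks.
#' @return Named list of integer depth vectors.
#' @export
load_depth <- function(path, lengths) {
  stopifnot(!is.null(names(lengths)), all(lengths >= 1))
  raw <- tryCatch(
    read.table(path, sep = "\t", header = FALSE,
               col.names = c("contig", "pos", "depth"),
               colClasses = c("character", "integer", "integer")),
    error = function(e) {
      if (file.exists(path) && length(readLines(path)) == 0L) {
        return(data.frame(contig = character(0), pos = integer(0),
                          depth = integer(0)))
      }
      stop("malformed depth file '", path, "': ", conditionMessage(e))
    })
  if (anyNA(raw$pos) || anyNA(raw$depth)) {
    bad <- which(is.na(raw$pos) | is.na(raw$depth))[1L]
    stop("malformed depth file '", path, "' at line ", bad)
  }
  if (any(raw$depth < 0)) {
    stop("negative depth at line ", which(raw$depth < 0)[1L])
  }
  unknown <- setdiff(unique(raw$contig), names(lengths))
  if (length(unknown)) {
    stop("contigs not in `lengths`: ", paste(unknown, collapse = ", "))
  }
  out <- lapply(names(lengths), function(ctg) {
    d <- integer(lengths[[ctg]])
    rows <- raw[raw$contig == ctg, , drop = FALSE]
    if (nrow(rows)) {
      if (is.unsorted(rows$pos, strictly = TRUE)) {
        stop("non-monotone positions within contig ", ctg)
      }
      if (max(rows$pos) > lengths[[ctg]]) {
        stop("position beyond declared length of contig ", ctg)
      }
      d[rows$pos] <- rows$depth
    }
    d
  })
  names(out) <- names(lengths)
  out
}
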