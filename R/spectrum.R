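# Indel size spectra and the large-deletion comparison.

#' Default indel size bins
#'
#' Size classes 1, 2-3, 4-6, 7-9 and >= 10 bp, chosen to expose the
#' NHEJ-typical 1-3 bp range, the > 7 bp microhomology analysis window, and
#' the >= 10 bp "large deletion" class.
#'
#' @return Numeric vector of lower bin edges (upper edge of the last bin is
#'   infinite).
#' @export
default_size_bins <- function() c(1, 2, 4, 7, 10)

bin_labels <- function(edges) {
  hi <- c(edges[-1] - 1, Inf)
  ifelse(is.infinite(hi), paste0(">=", edges),
         ifelse(hi == edges, as.character(edges), paste0(edges, "-", hi)))
}

#' Tally the indel size spectrum per chromosome class
#'
#' Counts deletions and insertions separately in the given size bins, for each
#' chromosome class, and reports the fraction of all indels in a class that
#' are deletions of at least `large_threshold` bp.
#'
#' @param records Indel records with `kind`, `length` or `size`, and
#'   `chrom_class` columns.
#' @param bins Lower bin edges (see [default_size_bins()]).
#' @param large_threshold Size threshold (bp) defining a "large" deletion.
#' @return List with `counts` (data.frame: `chrom_class`, `kind`, `bin`,
#'   `count`) and `large_deletion_fraction` (named vector per class; `NA` for
#'   classes with no indels).
#' @export
size_spectrum <- function(records, bins = default_size_bins(),
                          large_threshold = 10) {
  size <- if ("size" %in% names(records)) records$size else records$length
  if (!"chrom_class" %in% names(records)) {
    stop("records need a `chrom_class` column")
  }
  classes <- unique(records$chrom_class)
  labs <- bin_labels(bins)
  grid <- expand.grid(chrom_class = classes, kind = c("deletion", "insertion"),
                      bin = labs, stringsAsFactors = FALSE)
  bin_of <- labs[findInterval(size, bins)]
  key <- paste(records$chrom_class, records$kind, bin_of)
  tab <- table(key)
  grid$count <- as.integer(tab[paste(grid$chrom_class, grid$kind, grid$bin)])
  grid$count[is.na(grid$count)] <- 0L
  grid <- grid[order(grid$chrom_class, grid$kind, match(grid$bin, labs)), ]
  rownames(grid) <- NULL
  ldf <- vapply(classes, function(cl) {
    idx <- records$chrom_class == cl
    if (!any(idx)) return(NA_real_)
    sum(idx & records$kind == "deletion" & size >= large_threshold) / sum(idx)
  }, numeric(1))
  names(ldf) <- classes
  list(counts = grid, large_deletion_fraction = ldf)
}

#' Collapse indels shared across copies of one gene to single events
#'
#' Copies of a duplicated gene can carry the same ancestral indel; this keeps
#' one record per distinct (gene, kind, position, length) event so spectra are
#' not inflated by copy number.
#'
#' @param records Indel records with a `gene` column.
#' @return De-duplicated records.
#' @export
dedupe_indels <- function(records) {
  key <- paste(records$gene, records$kind, records$parent_pos, records$length)
  records[!duplicated(key), , drop = FALSE]
}

#' Compare large-deletion fractions between two groups of indels
#'
#' Builds the 2x2 table (>= `threshold` bp deletion vs any other indel) x
#' (group A vs B) and applies the Pearson chi-square test.
#'
#' @param a,b data.frames of indel records (columns `kind` and `length` or
#'   `size`); both must be non-empty.
#' @param threshold Deletion size threshold in bp.
#' @return List with `fractions` (length-2 named vector), `table` (2x2
#'   counts), and `test` (see [chi_square()]).
#' @export
compare_large_deletion_fraction <- function(a, b, threshold = 10) {
  if (nrow(a) == 0L || nrow(b) == 0L) stop("both groups must be non-empty")
  is_large <- function(d) {
    size <- if ("size" %in% names(d)) d$size else d$length
    d$kind == "deletion" & size >= threshold
  }
  la <- is_large(a)
  lb <- is_large(b)
  tab <- rbind(A = c(large_deletion = sum(la), other = sum(!la)),
               B = c(large_deletion = sum(lb), other = sum(!lb)))
  list(fractions = c(A = mean(la), B = mean(lb)), table = tab,
       test = chi_square(tab))
}
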