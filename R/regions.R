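# Assigning population indels to annotated regions and chromosome classes.

#' Default Drosophila chromosome-class map
#'
#' Maps chromosome arm names to the partition used for indel-spectrum
#' comparisons: major autosome arms, the X, and the dot (fourth) chromosome.
#'
#' @return Named character vector.
#' @export
drosophila_chrom_map <- function() {
  c(`2L` = "autosome", `2R` = "autosome", `3L` = "autosome", `3R` = "autosome",
    X = "X", `4` = "dot", Y = "Y")
}

#' Read a BED file of labeled regions
#'
#' @param path BED file (0-based half-open), 4th column = region class label
#'   (e.g. `intergenic`, `pseudogene`).
#' @return data.frame with `chrom`, `start`, `end`, `region_class`.
#' @export
read_regions_bed <- function(path) {
  b <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  if (ncol(b) < 4L) stop("BED must have >= 4 columns (4th = region class)")
  b <- b[, 1:4]
  names(b) <- c("chrom", "start", "end", "region_class")
  if (any(b$end <= b$start)) stop("BED regions must satisfy end > start")
  b
}

#' Annotate indel records with region and chromosome class
#'
#' Assigns each record to the region containing its (left-normalized) start:
#' the 1-based VCF position is converted to a 0-based point (`pos - 1`) and
#' tested against 0-based half-open BED intervals. Records outside all regions
#' are dropped. Chromosome class comes from `chrom_map`.
#'
#' @param records Records from [filter_vcf_indels()].
#' @param regions Labeled regions from [read_regions_bed()] (or an equivalent
#'   data.frame). Overlapping regions with conflicting labels are an error.
#' @param chrom_map Named vector mapping chromosome names to classes; see
#'   [drosophila_chrom_map()].
#' @return Subset of `records` with `region_class` and `chrom_class` added.
#' @export
annotate_regions <- function(records, regions,
                             chrom_map = drosophila_chrom_map()) {
  stopifnot(all(c("chrom", "start", "end", "region_class") %in% names(regions)))
  # conflicting-overlap check per chromosome
  for (ch in unique(regions$chrom)) {
    r <- regions[regions$chrom == ch, , drop = FALSE]
    ir <- IRanges::IRanges(start = r$start + 1L, end = r$end) # 1-based closed
    ov <- IRanges::findOverlaps(ir, ir)
    qh <- S4Vectors::queryHits(ov)
    sh <- S4Vectors::subjectHits(ov)
    bad <- qh < sh & r$region_class[qh] != r$region_class[sh]
    if (any(bad)) {
      off <- which(bad)[1L]
      stop(sprintf("overlapping regions with conflicting labels on %s: [%d,%d) %s vs [%d,%d) %s",
                   ch, r$start[qh[off]], r$end[qh[off]], r$region_class[qh[off]],
                   r$start[sh[off]], r$end[sh[off]], r$region_class[sh[off]]))
    }
  }
  if (nrow(records) == 0L) {
    records$region_class <- character(0)
    records$chrom_class <- character(0)
    return(records)
  }
  region_class <- rep(NA_character_, nrow(records))
  for (ch in unique(records$chrom)) {
    ridx <- which(records$chrom == ch)
    reg <- regions[regions$chrom == ch, , drop = FALSE]
    if (nrow(reg) == 0L) next
    pts <- IRanges::IRanges(start = records$pos[ridx], width = 1L) # 0-based pt pos-1 -> 1-based pos
    ir <- IRanges::IRanges(start = reg$start + 1L, end = reg$end)
    ov <- IRanges::findOverlaps(pts, ir, select = "first")
    region_class[ridx] <- reg$region_class[ov]
  }
  keep <- !is.na(region_class)
  out <- records[keep, , drop = FALSE]
  out$region_class <- region_class[keep]
  out$chrom_class <- unname(chrom_map[out$chrom])
  out
}
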