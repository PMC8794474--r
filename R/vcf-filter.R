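# Population indel filtering mirroring the vcftools pass used for the
# population comparison: --keep-only-indels --min-alleles 2 --max-alleles 2
# --maf <maf> plus --max-missing-count <n>.

parse_vcf_body <- function(path) {
  lines <- readLines(path)
  body <- lines[!startsWith(lines, "##")]
  if (length(body) == 0L || !startsWith(body[1L], "#CHROM")) {
    stop("not a VCF: missing #CHROM header line")
  }
  header <- strsplit(sub("^#", "", body[1L]), "\t", fixed = TRUE)[[1L]]
  if (length(header) < 10L || header[9L] != "FORMAT") {
    stop("VCF has no FORMAT/GT columns")
  }
  rows <- body[-1L]
  fields <- strsplit(rows, "\t", fixed = TRUE)
  list(samples = header[-(1:9)], fields = fields)
}

#' Filter population VCF records to analyzable biallelic indels
#'
#' Keeps biallelic indel records (one ALT allele, REF/ALT lengths differ) with
#' minor allele frequency at least `maf` computed over non-missing genotype
#' calls, and at most `max_missing_count` missing genotypes. Allele counting
#' is ploidy-agnostic: each GT field is split on `/` or `|` and every
#' non-missing allele call counts once, matching vcftools semantics. The `AF`
#' INFO field is never consulted.
#'
#' @param path VCF 4.x file with GT fields.
#' @param maf Minimum minor allele frequency.
#' @param max_missing_count Maximum number of samples with missing genotype.
#' @return data.frame with columns `chrom`, `pos` (1-based), `ref`, `alt`,
#'   `kind` (`deletion` if REF longer than ALT, else `insertion`), `size`
#'   (`abs(nchar(ref) - nchar(alt))`), `maf`, `n_missing`.
#' @export
filter_vcf_indels <- function(path, maf = 0.1, max_missing_count = Inf) {
  v <- parse_vcf_body(path)
  recs <- lapply(v$fields, function(f) {
    ref <- f[4L]
    alt <- f[5L]
    if (grepl(",", alt, fixed = TRUE) || alt == "." ||
        grepl("[^ACGTN]", ref) || grepl("[^ACGTN]", alt)) {
      return(NULL) # multiallelic, monomorphic or symbolic
    }
    if (nchar(ref) == nchar(alt)) return(NULL) # SNP/MNP, not an indel
    fmt <- strsplit(f[9L], ":", fixed = TRUE)[[1L]]
    gi <- match("GT", fmt)
    if (is.na(gi)) stop("missing GT in FORMAT at ", f[1L], ":", f[2L])
    gts <- vapply(f[-(1:9)],
                  function(x) strsplit(x, ":", fixed = TRUE)[[1L]][gi],
                  character(1), USE.NAMES = FALSE)
    alleles <- strsplit(gts, "[/|]")
    n_missing <- sum(vapply(alleles, function(a) all(a == "."), logical(1)))
    calls <- unlist(alleles)
    calls <- calls[calls != "."]
    if (length(calls) == 0L) return(NULL)
    f_alt <- mean(calls == "1")
    rec_maf <- min(f_alt, 1 - f_alt)
    if (rec_maf < maf || n_missing > max_missing_count) return(NULL)
    data.frame(chrom = f[1L], pos = as.integer(f[2L]), ref = ref, alt = alt,
               kind = if (nchar(ref) > nchar(alt)) "deletion" else "insertion",
               size = abs(nchar(ref) - nchar(alt)),
               maf = rec_maf, n_missing = n_missing, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, recs)
  if (is.null(out)) {
    out <- data.frame(chrom = character(0), pos = integer(0),
                      ref = character(0), alt = character(0),
                      kind = character(0), size = integer(0), maf = numeric(0),
                      n_missing = integer(0), stringsAsFactors = FALSE)
  }
  out
}
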