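#' Write a fixture VCF with exact allele frequencies
#'
#' Writes a minimal valid VCF 4.2 file whose haploid GT fields realize each
#' record's requested alternate-allele frequency exactly over the non-missing
#' samples. Allele assignment is deterministic in the counts; the seed only
#' shuffles which samples carry which allele.
#'
#' @param n_samples Number of sample columns.
#' @param records data.frame with columns `chrom`, `pos` (1-based), `ref`,
#'   `alt`, `af` (alternate-allele frequency over non-missing calls) and
#'   `missing` (number of missing genotypes). `af * (n_samples - missing)`
#'   must be a whole number; otherwise the combination is rejected.
#' @param path Output file path.
#' @param seed Integer seed.
#' @return `path`, invisibly.
#' @export
write_fixture_vcf <- function(n_samples, records, path, seed = NULL) {
  stopifnot(n_samples >= 1L)
  if (nrow(records) > 0L) {
    need <- c("chrom", "pos", "ref", "alt", "af", "missing")
    if (!all(need %in% names(records))) {
      stop("records must have columns: ", paste(need, collapse = ", "))
    }
    if (any(records$af < 0 | records$af > 1)) stop("af must be in [0, 1]")
    if (any(records$missing < 0 | records$missing > n_samples)) {
      stop("missing must be in [0, n_samples]")
    }
  }
  with_seed(seed, {
    header <- c(
      "##fileformat=VCFv4.2",
      "##source=ychrom_fixture",
      "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
      paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
              "FORMAT", paste0("s", seq_len(n_samples))), collapse = "\t")
    )
    body <- character(0)
    if (nrow(records) > 0L) {
      body <- vapply(seq_len(nrow(records)), function(i) {
        r <- records[i, ]
        n_called <- n_samples - r$missing
        n_alt <- r$af * n_called
        if (abs(n_alt - round(n_alt)) > 1e-9) {
          stop(sprintf("record %d: af %.4g not realizable over %d called samples",
                       i, r$af, n_called))
        }
        n_alt <- as.integer(round(n_alt))
        gt <- c(rep(".", r$missing), rep("1", n_alt),
                rep("0", n_called - n_alt))
        gt <- gt[sample.int(n_samples)]
        paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".", "PASS", ".", "GT", gt),
              collapse = "\t")
      }, character(1))
    }
    writeLines(c(header, body), path)
    invisible(path)
  })
}
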