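# Internal randomness helpers. Every exported generator takes an explicit
# `seed`; the global RNG state is saved and restored so callers' streams are
# never disturbed.

with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      old <- get(".Random.seed", envir = globalenv())
      on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    } else {
      on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
    }
    set.seed(as.integer(seed))
  }
  force(code)
}

DNA_BASES <- c("A", "C", "G", "T")

# Random DNA as a character vector of single bases.
random_bases <- function(n, gc = 0.5) {
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  sample(DNA_BASES, n, replace = TRUE, prob = p)
}

#' Random DNA string
#'
#' Uses the caller's RNG stream (no seed argument); wrap in `set.seed()` for
#' reproducibility.
#'
#' @param n Length in bp.
#' @param gc GC fraction.
#' @return A DNA string of length `n`.
#' @export
random_dna <- function(n, gc = 0.5) paste(random_bases(n, gc), collapse = "")

# A base different from `b` (vectorized over b).
other_base <- function(b) {
  vapply(b, function(x) sample(setdiff(DNA_BASES, x), 1L), character(1),
         USE.NAMES = FALSE)
}

# Longest common prefix / suffix length of two character vectors of bases.
lcp_len <- function(a, b) {
  n <- min(length(a), length(b))
  if (n == 0L) return(0L)
  neq <- which(a[seq_len(n)] != b[seq_len(n)])
  if (length(neq) == 0L) n else neq[1L] - 1L
}

lcs_len <- function(a, b) lcp_len(rev(a), rev(b))

chars <- function(s) strsplit(s, "", fixed = TRUE)[[1L]]
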