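# Four-gamete incompatibilities and the Hudson-Kaplan minimum number of
# recombination events (Rmin) among ampliconic gene copies, with indel
# presence/absence included as characters.

#' Encode an alignment as a haplotype matrix
#'
#' Biallelic SNP columns (no gaps, exactly two bases among non-N calls) are
#' encoded 0/1 with the major allele as 0 (ties broken toward the allele seen
#' first in sequence order). When `include_indels` is true, each distinct gap
#' run (same start column and length) segregating among the sequences becomes
#' one presence/absence character at its start column; sequences whose gaps
#' partially overlap a run without matching it exactly are missing (`NA`) for
#' that character. Columns with more than two alleles and invariant columns
#' are dropped.
#'
#' @param aln An `aligned_set`.
#' @param include_indels Include indel presence/absence characters?
#' @return Object of class `haplotype_matrix`: list with `matrix` (0/1/NA,
#'   rows = sequences) and `positions` (alignment columns, increasing).
#' @export
encode_alignment <- function(aln, include_indels = TRUE) {
  stopifnot(inherits(aln, "aligned_set"))
  if (length(aln$seqs) < 2L) stop("need >= 2 sequences")
  M <- do.call(rbind, lapply(aln$seqs, chars))
  n <- nrow(M)
  cols <- list()
  pos <- integer(0)
  # SNP columns
  for (j in seq_len(ncol(M))) {
    x <- M[, j]
    if (any(x == "-")) next
    known <- x != "N"
    al <- unique(x[known])
    if (length(al) != 2L) next
    counts <- c(sum(x == al[1L]), sum(x == al[2L]))
    major <- al[which.max(counts)] # first allele wins ties
    g <- ifelse(known, as.integer(x != major), NA_integer_)
    cols[[length(cols) + 1L]] <- g
    pos <- c(pos, j)
  }
  if (include_indels) {
    # gap runs per sequence: (start, length) pairs
    runs <- lapply(seq_len(n), function(i) {
      r <- rle(M[i, ] == "-")
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      data.frame(start = starts[r$values], len = r$lengths[r$values])
    })
    all_runs <- unique(do.call(rbind, runs))
    if (!is.null(all_runs) && nrow(all_runs) > 0L) {
      all_runs <- all_runs[order(all_runs$start, all_runs$len), , drop = FALSE]
      for (k in seq_len(nrow(all_runs))) {
        s <- all_runs$start[k]
        l <- all_runs$len[k]
        g <- vapply(seq_len(n), function(i) {
          ri <- runs[[i]]
          if (any(ri$start == s & ri$len == l)) return(1L)
          # overlapping but different gap: state unknowable
          if (any(ri$start < s + l & ri$start + ri$len > s)) return(NA_integer_)
          0L
        }, integer(1))
        if (length(unique(g[!is.na(g)])) == 2L) {
          cols[[length(cols) + 1L]] <- g
          pos <- c(pos, s)
        }
      }
    }
  }
  if (length(cols) == 0L) {
    warning("fewer than 2 usable sites; empty haplotype matrix")
    H <- matrix(integer(0), nrow = n, ncol = 0,
                dimnames = list(names(aln$seqs), NULL))
    return(structure(list(matrix = H, positions = integer(0)),
                     class = "haplotype_matrix"))
  }
  ord <- order(pos)
  H <- do.call(cbind, cols)[, ord, drop = FALSE]
  rownames(H) <- names(aln$seqs)
  structure(list(matrix = H, positions = pos[ord]),
            class = "haplotype_matrix")
}

as_haplotype_matrix <- function(H) {
  if (inherits(H, "haplotype_matrix")) return(H)
  if (is.matrix(H)) {
    return(structure(list(matrix = H, positions = seq_len(ncol(H))),
                     class = "haplotype_matrix"))
  }
  if (is.list(H) && !is.null(H$matrix)) {
    p <- if (!is.null(H$positions)) H$positions else seq_len(ncol(H$matrix))
    return(structure(list(matrix = H$matrix, positions = p),
                     class = "haplotype_matrix"))
  }
  stop("cannot interpret input as a haplotype matrix")
}

# All four gametes 00/01/10/11 present between columns i and j over
# pairwise-complete rows?
four_gametes <- function(a, b) {
  ok <- !is.na(a) & !is.na(b)
  length(unique(a[ok] * 2L + b[ok])) == 4L
}

#' Find all four-gamete incompatible site pairs
#'
#' A pair of biallelic sites exhibiting all four gametes among haplotypes
#' non-missing at both sites cannot be explained by unique mutation on a
#' single tree: it implies recombination or gene conversion between the
#' sites.
#'
#' @param H A `haplotype_matrix` (from [encode_alignment()] or
#'   [simulate_haplotypes()]; a plain 0/1 matrix is accepted, with positions
#'   taken as column indices).
#' @return data.frame with `site_i`, `site_j` (column indices, `i < j`) and
#'   `pos_i`, `pos_j`.
#' @export
four_gamete_pairs <- function(H) {
  H <- as_haplotype_matrix(H)
  m <- ncol(H$matrix)
  res <- list()
  if (m >= 2L) for (i in seq_len(m - 1L)) {
    a <- H$matrix[, i]
    for (j in (i + 1L):m) {
      if (four_gametes(a, H$matrix[, j])) {
        res[[length(res) + 1L]] <- c(i, j)
      }
    }
  }
  if (length(res) == 0L) {
    return(data.frame(site_i = integer(0), site_j = integer(0),
                      pos_i = integer(0), pos_j = integer(0)))
  }
  ij <- do.call(rbind, res)
  data.frame(site_i = ij[, 1L], site_j = ij[, 2L],
             pos_i = H$positions[ij[, 1L]], pos_j = H$positions[ij[, 2L]])
}

#' Hudson-Kaplan minimum number of recombination events
#'
#' Each four-gamete incompatible pair requires at least one recombination (or
#' gene-conversion breakpoint) strictly between its two sites. Reducing the
#' pairs to open intervals and taking the maximum set of pairwise-disjoint
#' intervals (greedy by right endpoint, which is optimal for interval
#' packing) gives the Hudson-Kaplan lower bound Rmin.
#'
#' @inheritParams four_gamete_pairs
#' @return Integer Rmin.
#' @export
rmin <- function(H) {
  H <- as_haplotype_matrix(H)
  pairs <- four_gamete_pairs(H)
  if (nrow(pairs) == 0L) return(0L)
  iv <- pairs[order(pairs$pos_j, pairs$pos_i), c("pos_i", "pos_j")]
  count <- 0L
  last_end <- -Inf
  for (k in seq_len(nrow(iv))) {
    if (iv$pos_i[k] >= last_end) { # open intervals: touching is disjoint
      count <- count + 1L
      last_end <- iv$pos_j[k]
    }
  }
  count
}

#' Descriptive gene-conversion summary for an aligned gene family
#'
#' Reports Rmin, Rmin per kb, the number of incompatible site pairs, and the
#' mean pairwise identity among copies (the "gene similarity" signal:
#' 1 minus the mean pairwise difference count over the alignment length).
#' Per-generation conversion rates are deliberately not derived — they require
#' population-genetic assumptions beyond the data; Rmin is the defensible
#' lower bound on conversion activity.
#'
#' @inheritParams four_gamete_pairs
#' @param alignment_length Alignment length in bp (> 0).
#' @return List with `rmin`, `rmin_per_kb`, `n_incompatible_pairs`,
#'   `mean_pairwise_identity`.
#' @export
conversion_summary <- function(H, alignment_length) {
  if (alignment_length <= 0) stop("alignment_length must be > 0")
  H <- as_haplotype_matrix(H)
  pairs <- four_gamete_pairs(H)
  r <- rmin(H)
  G <- H$matrix
  n <- nrow(G)
  diffs <- 0
  npairs <- 0L
  if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    ok <- !is.na(G[i, ]) & !is.na(G[j, ])
    diffs <- diffs + sum(G[i, ok] != G[j, ok])
    npairs <- npairs + 1L
  }
  mean_diff <- if (npairs > 0L) diffs / npairs else 0
  list(rmin = r,
       rmin_per_kb = r / (alignment_length / 1000),
       n_incompatible_pairs = nrow(pairs),
       mean_pairwise_identity = 1 - mean_diff / alignment_length)
}
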