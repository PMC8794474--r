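# Independent oracles and fixture builders used across tests.

# Exhaustive maximum set of pairwise-disjoint open intervals, by
# include/exclude recursion with a simple bound. Independent of the greedy
# sweep used by rmin().
oracle_max_disjoint <- function(a, b) {
  if (length(a) == 0L) return(0L)
  best <- 0L
  rec <- function(idx, last_end, count) {
    if (count + length(idx) <= best) return(invisible())
    if (length(idx) == 0L) {
      best <<- max(best, count)
      return(invisible())
    }
    i <- idx[1L]
    rec(idx[-1L], last_end, count)
    if (a[i] >= last_end) rec(idx[-1L], b[i], count + 1L)
  }
  rec(order(b), -Inf, 0L)
  best
}

# Brute-force four-gamete enumeration via explicit gamete strings.
oracle_four_gamete_pairs <- function(M) {
  out <- NULL
  if (ncol(M) >= 2L) for (i in 1:(ncol(M) - 1L)) for (j in (i + 1L):ncol(M)) {
    g <- paste0(M[, i], M[, j])
    g <- g[!grepl("NA", g, fixed = TRUE)]
    if (all(c("00", "01", "10", "11") %in% g)) out <- rbind(out, c(i, j))
  }
  out
}

# Monte-Carlo permutation p for a Pearson statistic under fixed margins.
oracle_mc_chisq <- function(tab, n_draws = 200000L) {
  obs <- {
    E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
    sum((tab - E)^2 / E)
  }
  sim <- stats::r2dtable(n_draws, rowSums(tab), colSums(tab))
  ss <- vapply(sim, function(m) {
    E <- outer(rowSums(m), colSums(m)) / sum(m)
    sum((m - E)^2 / E)
  }, numeric(1))
  p <- mean(ss >= obs - 1e-9)
  list(p = p, se = sqrt(p * (1 - p) / n_draws))
}

# Random, classifier-consistent indel spec (mechanism rules respected so
# planted truth is recoverable exactly).
random_indel_spec <- function(n) {
  rows <- lapply(seq_len(n), function(i) {
    mech <- sample(c("NHEJ-like", "MMEJ-like", "slippage"), 1L)
    if (mech == "NHEJ-like") {
      L <- sample(1:3, 1L)
      m <- sample(0:max(0L, L - 1L), 1L)
    } else if (mech == "MMEJ-like") {
      L <- sample(4:15, 1L)
      m <- if (L > 7L) sample(2:min(6L, L - 1L), 1L) else sample(0:(L - 1L), 1L)
    } else {
      L <- sample(2:8, 1L)
      m <- L
    }
    data.frame(kind = sample(c("deletion", "insertion"), 1L),
               length = L, microhomology = m, mechanism = mech,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# Indel records with an exactly planted large-deletion fraction.
planted_fraction_group <- function(n, frac, threshold = 10) {
  n_large <- round(n * frac)
  kind <- c(rep("deletion", n_large),
            sample(c("deletion", "insertion"), n - n_large, replace = TRUE))
  len <- c(sample(threshold:30, n_large, replace = TRUE),
           sample(1:(threshold - 1), n - n_large, replace = TRUE))
  idx <- sample.int(n)
  data.frame(kind = kind[idx], length = len[idx], stringsAsFactors = FALSE)
}
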