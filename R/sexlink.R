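# Y-linkage assignment from male vs female depth.
#
# A window is called Y-linked when the median per-site female/male depth ratio
# is at (or below) fm_max and male depth is high enough to be informative.
# Sites with zero male depth carry no information about female/male ratio and
# are excluded; windows with no informative site are "ambiguous".

window_partition <- function(n, window) {
  if (n <= window) return(data.frame(start = 0L, end = as.integer(n)))
  n_full <- n %/% window
  starts <- (seq_len(n_full) - 1L) * window
  ends <- starts + window
  r <- n - n_full * window
  if (r > 0L) {
    if (r < window / 2) {
      ends[n_full] <- n # merge trailing partial into previous window
    } else {
      starts <- c(starts, n_full * window)
      ends <- c(ends, n)
    }
  }
  data.frame(start = as.integer(starts), end = as.integer(ends))
}

#' Library-size normalization factors from autosomal depth
#'
#' Computes each sex's median per-site depth over autosomal contigs. Dividing
#' a library's depths by its factor puts both sexes on a common scale;
#' `female_rescale = male_factor / female_factor` is the multiplier applied to
#' female depths by downstream functions so that autosomal female/male is ~1
#' while male depths stay on their raw scale.
#'
#' @param male,female Named lists of per-contig depth vectors.
#' @param autosome_ids Contig names to treat as autosomal.
#' @return List with `male_factor`, `female_factor`, `female_rescale`.
#' @export
normalize_libraries <- function(male, female, autosome_ids) {
  if (length(autosome_ids) == 0L) stop("at least one autosomal contig required")
  missing <- setdiff(autosome_ids, intersect(names(male), names(female)))
  if (length(missing)) {
    stop("autosomal contigs absent from tracks: ", paste(missing, collapse = ", "))
  }
  mf <- median(unlist(male[autosome_ids], use.names = FALSE))
  ff <- median(unlist(female[autosome_ids], use.names = FALSE))
  if (mf == 0 || ff == 0) stop("zero autosomal median depth")
  list(male_factor = mf, female_factor = ff, female_rescale = mf / ff)
}

#' Windowed male/female coverage statistics
#'
#' Splits each contig into fixed windows (default 10 kb; a trailing partial
#' window shorter than half the span is merged into the previous window,
#' otherwise kept) and summarizes male and female depth per window. The
#' female/male ratio is the median of per-site `female/male` over sites with
#' male depth > 0.
#'
#' @param male,female Named lists of per-contig depth vectors covering the
#'   same contigs.
#' @param window Window span in bp (0-based half-open coordinates).
#' @param female_rescale Multiplier applied to female depths before the ratio
#'   (see [normalize_libraries()]).
#' @return data.frame with columns `contig`, `start`, `end`, `male_median`,
#'   `female_median`, `fm_ratio`, `n_informative`.
#' @export
window_stats <- function(male, female, window = 10000, female_rescale = 1) {
  if (!setequal(names(male), names(female))) {
    stop("male and female tracks must cover the same contigs")
  }
  out <- lapply(names(male), function(ctg) {
    dm <- male[[ctg]]
    df <- female[[ctg]]
    if (length(dm) != length(df)) {
      stop("male and female tracks differ in length on contig ", ctg)
    }
    win <- window_partition(length(dm), window)
    stats <- t(vapply(seq_len(nrow(win)), function(i) {
      idx <- (win$start[i] + 1L):win$end[i]
      m <- dm[idx]
      f <- df[idx] * female_rescale
      inf <- m > 0
      c(male_median = median(m), female_median = median(f),
        fm_ratio = if (any(inf)) median(f[inf] / m[inf]) else NA_real_,
        n_informative = sum(inf))
    }, numeric(4)))
    cbind(data.frame(contig = ctg), win, as.data.frame(stats))
  })
  do.call(rbind, out)
}

#' Classify windows as Y-linked or not
#'
#' A window is `Y` when `fm_ratio <= fm_max` and `male_median >=
#' min_male_depth`; `ambiguous` when the ratio is undefined (no site with male
#' depth) or male median depth is below `min_male_depth` (too little male
#' signal to distinguish Y-linked from unmappable sequence); otherwise
#' `non-Y`.
#'
#' @param stats A [window_stats()] table.
#' @param fm_max Maximum female/male ratio for a Y call. The strict criterion
#'   "median female/male ratio equals zero" is the limit `fm_max = 0`; the
#'   default 0.1 tolerates mismapping noise.
#' @param min_male_depth Minimum male median depth for a confident call.
#' @return `stats` with a `call` column added.
#' @export
classify_windows <- function(stats, fm_max = 0.1, min_male_depth = 5) {
  call <- ifelse(is.na(stats$fm_ratio) | stats$male_median < min_male_depth,
                 "ambiguous",
                 ifelse(stats$fm_ratio <= fm_max, "Y", "non-Y"))
  stats$call <- call
  stats
}

#' Female-to-male total mapped-base ratio per contig
#'
#' @inheritParams window_stats
#' @return Named numeric vector, `sum(female) / sum(male)` per contig
#'   (`Inf` when a contig has zero male depth).
#' @export
contig_read_ratio <- function(male, female, female_rescale = 1) {
  vapply(names(male), function(ctg) {
    sum(as.numeric(female[[ctg]])) * female_rescale /
      sum(as.numeric(male[[ctg]]))
  }, numeric(1))
}

#' Aggregate window calls into contig-level Y assignments
#'
#' A contig is called `Y` when the median window `fm_ratio` (over windows with
#' a defined ratio) is at most `fm_max`, and, when the extra criterion is on,
#' its female-to-male total mapped-base ratio is below `fm_reads_max`. The
#' extra criterion guards against contigs that pass the window rule through
#' mismapping (the failure mode seen when male and female libraries differ in
#' construction).
#'
#' @param stats A [classify_windows()] table.
#' @param read_ratio Named vector from [contig_read_ratio()] (required when
#'   `extra_criterion = TRUE`).
#' @param fm_max Maximum median window ratio for a Y call.
#' @param extra_criterion Apply the whole-contig read-ratio criterion?
#' @param fm_reads_max Threshold for the read-ratio criterion.
#' @return data.frame with `contig`, `median_fm`, `read_ratio`, `call`.
#' @export
classify_contigs <- function(stats, read_ratio = NULL, fm_max = 0.1,
                             extra_criterion = FALSE, fm_reads_max = 0.1) {
  if (extra_criterion && is.null(read_ratio)) {
    stop("extra_criterion requires `read_ratio`")
  }
  contigs <- unique(stats$contig)
  out <- lapply(contigs, function(ctg) {
    s <- stats[stats$contig == ctg, , drop = FALSE]
    med <- median(s$fm_ratio, na.rm = TRUE)
    rr <- if (!is.null(read_ratio)) unname(read_ratio[ctg]) else NA_real_
    call <- if (is.na(med)) {
      "ambiguous"
    } else if (med <= fm_max && (!extra_criterion || rr < fm_reads_max)) {
      "Y"
    } else {
      "non-Y"
    }
    data.frame(contig = ctg, median_fm = med, read_ratio = rr, call = call,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, out)
}

#' Score Y calls against truth labels
#'
#' Sensitivity is `TP / (TP + FN)` over truly Y-linked units and the
#' false-positive rate is `FP / (FP + TN)` over truly non-Y units. Units
#' called `ambiguous` are excluded from both.
#'
#' @param calls Character vector of calls (`"Y"`, `"non-Y"`, `"ambiguous"`).
#' @param truth Character vector of true classes; `"Y"` is positive, anything
#'   else negative.
#' @return List with `sensitivity`, `false_positive_rate`, and `counts`
#'   (named TP/FP/TN/FN/ambiguous).
#' @export
evaluate_assignments <- function(calls, truth) {
  if (length(truth) == 0L) stop("empty truth")
  if (length(calls) != length(truth)) stop("calls and truth lengths differ")
  amb <- calls == "ambiguous"
  calls <- calls[!amb]
  truth <- truth[!amb]
  pos <- truth == "Y"
  tp <- sum(calls == "Y" & pos)
  fn <- sum(calls != "Y" & pos)
  fp <- sum(calls == "Y" & !pos)
  tn <- sum(calls != "Y" & !pos)
  list(
    sensitivity = if (tp + fn > 0) tp / (tp + fn) else NA_real_,
    false_positive_rate = if (fp + tn > 0) fp / (fp + tn) else NA_real_,
    counts = c(TP = tp, FP = fp, TN = tn, FN = fn, ambiguous = sum(amb))
  )
}
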