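# Indel extraction from duplicate-vs-parent alignments, breakpoint
# microhomology, and repair-mechanism classification.

# Shift an indel to its leftmost equivalent placement on the ungapped parent
# (VCF-style left alignment). P is the parent as a character vector (1-based);
# pos is 0-based.
left_normalize_deletion <- function(P, pos, L) {
  while (pos >= 1L && P[pos] == P[pos + L]) pos <- pos - 1L
  list(pos = pos, seq = paste(P[(pos + 1L):(pos + L)], collapse = ""))
}

left_normalize_insertion <- function(P, pos, seg) {
  L <- length(seg)
  while (pos >= 1L && seg[L] == P[pos]) {
    seg <- c(P[pos], seg[-L])
    pos <- pos - 1L
  }
  list(pos = pos, seq = paste(seg, collapse = ""))
}

#' Extract indel records from a duplicate-vs-parent alignment
#'
#' Finds maximal gap runs in each copy-vs-parent pairwise projection of the
#' alignment: gaps in the copy are deletions, gaps in the parent are
#' insertions (both relative to the parent). Adjacent runs separated by at
#' least one aligned column are distinct events. Positions are reported on the
#' ungapped parent and left-normalized, so an event placed anywhere within its
#' microhomology tract by the aligner yields the same canonical record.
#'
#' @param aln An `aligned_set` with a designated parent.
#' @param keep_terminal_gaps Keep gap runs touching the first or last
#'   alignment column? Default drops them as likely truncation artifacts.
#' @return data.frame with columns `copy_id`, `kind`, `parent_pos` (0-based),
#'   `length`, `seq` (deleted/inserted segment at the normalized placement).
#' @export
extract_indels <- function(aln, keep_terminal_gaps = FALSE) {
  stopifnot(inherits(aln, "aligned_set"))
  if (is.null(aln$parent_id)) stop("alignment has no designated parent")
  pg_full <- chars(aln$seqs[[aln$parent_id]])
  copies <- setdiff(names(aln$seqs), aln$parent_id)
  out <- lapply(copies, function(cid) {
    cg_full <- chars(aln$seqs[[cid]])
    both <- pg_full == "-" & cg_full == "-"
    pg <- pg_full[!both]
    cg <- cg_full[!both]
    ncol <- length(pg)
    P <- pg[pg != "-"]
    pcount <- cumsum(pg != "-") # parent bases consumed through each column
    recs <- list()
    for (kind in c("deletion", "insertion")) {
      mask <- if (kind == "deletion") cg == "-" else pg == "-"
      r <- rle(mask)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths + 1L
      runs <- which(r$values)
      for (j in runs) {
        a <- starts[j]; b <- ends[j]
        if (!keep_terminal_gaps && (a == 1L || b == ncol)) next
        if (kind == "deletion") {
          pos <- pcount[a] - 1L
          ln <- left_normalize_deletion(P, pos, b - a + 1L)
        } else {
          pos <- pcount[a]
          ln <- left_normalize_insertion(P, pos, cg[a:b])
        }
        recs[[length(recs) + 1L]] <- data.frame(
          copy_id = cid, kind = kind, parent_pos = ln$pos,
          length = b - a + 1L, seq = ln$seq, stringsAsFactors = FALSE)
      }
    }
    if (length(recs)) do.call(rbind, recs) else NULL
  })
  out <- do.call(rbind, out)
  if (is.null(out)) {
    out <- data.frame(copy_id = character(0), kind = character(0),
                      parent_pos = integer(0), length = integer(0),
                      seq = character(0), stringsAsFactors = FALSE)
  }
  out[order(out$copy_id, out$parent_pos), , drop = FALSE]
}

#' Measure breakpoint microhomology
#'
#' For a deletion of segment `D` with left flank `L` and right flank `R`, the
#' microhomology is `max(lcp(D, R), lcs(D, L))` capped at the event length,
#' where `lcp`/`lcs` are the longest common prefix/suffix; insertions use the
#' inserted segment against the same flanks. This is the single-junction
#' identity a microhomology-mediated end-joining event would have annealed at.
#'
#' @param parent Ungapped parent DNA string.
#' @param records Indel records from [extract_indels()] (coordinates must be
#'   valid on `parent`).
#' @return Integer vector of microhomology lengths, one per record.
#' @export
measure_microhomology <- function(parent, records) {
  P <- chars(ungap(parent))
  n <- length(P)
  vapply(seq_len(nrow(records)), function(i) {
    pos <- records$parent_pos[i]
    L <- records$length[i]
    seg <- chars(records$seq[i])
    if (pos < 0L || pos > n ||
        (records$kind[i] == "deletion" && pos + L > n)) {
      stop("record ", i, ": coordinates out of range on parent")
    }
    rstart <- if (records$kind[i] == "deletion") pos + L else pos
    R <- if (rstart < n) P[(rstart + 1L):n] else character(0)
    Lf <- if (pos > 0L) P[seq_len(pos)] else character(0)
    min(L, max(lcp_len(seg, R), lcs_len(seg, Lf)))
  }, integer(1))
}

#' Classify the likely double-strand-break repair mechanism
#'
#' An event whose segment exactly equals an adjacent parent segment of the
#' same length is a tandem duplication / polymerase-slippage product. Other
#' events are classified by size: 1-3 bp events are NHEJ-like, > 3 bp events
#' are MMEJ-like, except that events longer than 7 bp additionally require
#' microhomology >= 2 bp for the MMEJ call (size alone is not evidence at
#' those lengths) and are otherwise unclassified.
#'
#' @param parent Ungapped parent DNA string.
#' @param records Indel records with a `microhomology` column (see
#'   [measure_microhomology()]).
#' @return Character vector of mechanism calls: `"slippage/tandem-dup"`,
#'   `"NHEJ-like"`, `"MMEJ-like"` or `"unclassified"`.
#' @export
classify_mechanism <- function(parent, records) {
  if (!"microhomology" %in% names(records)) {
    stop("records need a `microhomology` column; run measure_microhomology()")
  }
  P <- chars(ungap(parent))
  n <- length(P)
  vapply(seq_len(nrow(records)), function(i) {
    pos <- records$parent_pos[i]
    L <- records$length[i]
    m <- records$microhomology[i]
    seg <- chars(records$seq[i])
    rstart <- if (records$kind[i] == "deletion") pos + L else pos
    right <- rstart + L <= n && identical(P[(rstart + 1L):(rstart + L)], seg)
    left <- pos - L >= 0L && identical(P[(pos - L + 1L):pos], seg)
    if (right || left) return("slippage/tandem-dup")
    if (L <= 3L) return("NHEJ-like")
    if (L <= 7L || m >= 2L) return("MMEJ-like")
    "unclassified"
  }, character(1))
}

#' Fill microhomology and mechanism for extracted indel records
#'
#' Convenience wrapper: runs [measure_microhomology()] then
#' [classify_mechanism()].
#'
#' @inheritParams measure_microhomology
#' @return `records` with `microhomology` and `mechanism` columns.
#' @export
annotate_indels <- function(parent, records) {
  records$microhomology <- measure_microhomology(parent, records)
  records$mechanism <- classify_mechanism(parent, records)
  records
}

#' Classify indels as shared between species or species-specific
#'
#' Two records are the same indel when they match on gene, kind,
#' left-normalized parent position and length (exact identity; no chaining of
#' near-identical events). An indel observed in copies from more than one
#' species is `shared`; genes represented by a single species get `NA`.
#'
#' @param records Indel records with a `gene` column.
#' @param species Named character vector mapping `copy_id` to species.
#' @return `records` with a `sharing` column (`"shared"`,
#'   `"species-specific"`, or `NA`).
#' @export
classify_sharing <- function(records, species) {
  if (!"gene" %in% names(records)) stop("records need a `gene` column")
  miss <- setdiff(unique(records$copy_id), names(species))
  if (length(miss)) {
    stop("copies without species label: ", paste(miss, collapse = ", "))
  }
  sp <- species[records$copy_id]
  key <- paste(records$gene, records$kind, records$parent_pos, records$length)
  sharing <- rep(NA_character_, nrow(records))
  for (g in unique(records$gene)) {
    idx <- records$gene == g
    if (length(unique(sp[idx])) < 2L) next # single-species gene: NA
    nsp <- tapply(sp[idx], key[idx], function(x) length(unique(x)))
    sharing[idx] <- ifelse(nsp[key[idx]] > 1L, "shared", "species-specific")
  }
  records$sharing <- sharing
  records
}
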