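# Planting indels with exact, testable truth.
#
# Microhomology is planted by editing flank bases: for a deletion of segment D
# with right flank R, the first m bases of R are set equal to the first m
# bases of D (and base m+1 forced to differ), giving junction identity of
# exactly m; the base left of the event is forced to differ from the last base
# of the segment, which both zeroes the left-directional match and makes the
# planted position the left-normalized (leftmost equivalent) placement.

validate_indel_specs <- function(specs) {
  stopifnot(is.data.frame(specs))
  need <- c("kind", "length", "microhomology", "mechanism")
  if (!all(need %in% names(specs))) {
    stop("specs must have columns: ", paste(need, collapse = ", "))
  }
  if (nrow(specs) == 0L) return(invisible(specs))
  if (!all(specs$kind %in% c("deletion", "insertion"))) {
    stop("kind must be 'deletion' or 'insertion'")
  }
  if (!all(specs$mechanism %in% c("NHEJ-like", "MMEJ-like", "slippage"))) {
    stop("mechanism must be 'NHEJ-like', 'MMEJ-like' or 'slippage'")
  }
  if (any(specs$length < 1L)) stop("indel length must be >= 1")
  if (any(specs$microhomology < 0L | specs$microhomology > specs$length)) {
    stop("microhomology must be in [0, length]")
  }
  ns <- specs$mechanism != "slippage"
  if (any(ns & specs$microhomology >= specs$length)) {
    stop("non-slippage specs need microhomology < length: at equality the ",
         "segment matches an adjacent parent segment, i.e. is slippage")
  }
  bad_nhej <- specs$mechanism == "NHEJ-like" &
    (specs$length < 1L | specs$length > 3L)
  if (any(bad_nhej)) stop("NHEJ-like events must be 1-3 bp")
  bad_mmej <- specs$mechanism == "MMEJ-like" &
    !(specs$length > 3L & (specs$length <= 7L | specs$microhomology >= 2L))
  if (any(bad_mmej)) {
    stop("MMEJ-like events must be > 3 bp, and > 7 bp events need ",
         "microhomology >= 2")
  }
  invisible(specs)
}

#' Plant indels between a parent sequence and a derived duplicate
#'
#' Creates a derived copy of `parent` carrying the requested indels at
#' non-overlapping sites, editing flank bases of the parent where needed so
#' that each event's junction microhomology is exactly as requested and its
#' recorded position is already left-normalized. Slippage events duplicate
#' (insertion) or collapse (deletion) an exact tandem copy of the adjacent
#' parent segment; their truth microhomology equals the event length by
#' construction.
#'
#' @param parent DNA string (A/C/G/T) hosting the events. Flank bases may be
#'   edited; the edited parent is returned and is the sequence all truth
#'   coordinates refer to.
#' @param specs data.frame with columns `kind` (`"deletion"`/`"insertion"`),
#'   `length` (bp), `microhomology` (bp, `< length` unless slippage) and
#'   `mechanism` (`"NHEJ-like"`, `"MMEJ-like"`, `"slippage"`). Specs must be
#'   consistent with the mechanism classifier's rules (1-3 bp for NHEJ-like;
#'   > 3 bp, and microhomology >= 2 when > 7 bp, for MMEJ-like).
#' @param seed Integer seed.
#'
#' @return Object of class `planted_indels`: list with `parent` (edited),
#'   `derived`, and `truth` (data.frame `kind`, `parent_pos` 0-based
#'   left-normalized, `length`, `seq`, `microhomology`, `mechanism`).
#' @export
#'
#' @examples
#' specs <- data.frame(kind = "deletion", length = 12, microhomology = 2,
#'                     mechanism = "MMEJ-like")
#' p <- plant_duplicate_indels(random_dna <- paste(rep("ACGT", 30), collapse = ""),
#'                             specs, seed = 1)
#' p$truth
plant_duplicate_indels <- function(parent, specs, seed = NULL) {
  stopifnot(is.character(parent), length(parent) == 1L)
  validate_indel_specs(specs)
  P <- chars(toupper(parent))
  if (!all(P %in% DNA_BASES)) stop("parent must contain only A/C/G/T")
  n <- length(P)
  if (nrow(specs) == 0L) {
    truth <- data.frame(kind = character(0), parent_pos = integer(0),
                        length = integer(0), seq = character(0),
                        microhomology = integer(0), mechanism = character(0),
                        stringsAsFactors = FALSE)
    return(structure(list(parent = paste(P, collapse = ""),
                          derived = paste(P, collapse = ""), truth = truth),
                     class = "planted_indels"))
  }
  with_seed(seed, {
    truth <- vector("list", nrow(specs))
    cursor <- 1L # 1-based index of next unreserved parent base
    for (i in seq_len(nrow(specs))) {
      kind <- specs$kind[i]
      L <- as.integer(specs$length[i])
      m <- as.integer(specs$microhomology[i])
      mech <- specs$mechanism[i]
      spacer <- 8L + sample.int(8L, 1L)
      cursor <- cursor + spacer
      if (mech == "slippage") {
        span <- if (kind == "insertion") L else 2L * L
        # [tpos, tpos+L) template (1-based tpos); guards on both sides
        tpos <- cursor + 1L # leave cursor as left guard
        if (tpos + span > n) stop("parent too short to host all specs disjointly")
        if (kind == "deletion") {
          P[(tpos + L):(tpos + 2L * L - 1L)] <- P[tpos:(tpos + L - 1L)]
        }
        tmpl <- P[tpos:(tpos + L - 1L)]
        if (P[tpos - 1L] == tmpl[L]) P[tpos - 1L] <- other_base(tmpl[L])
        if (P[tpos + span] == tmpl[1L]) P[tpos + span] <- other_base(tmpl[1L])
        truth[[i]] <- data.frame(
          kind = kind, parent_pos = tpos - 1L, length = L,
          seq = paste(tmpl, collapse = ""), microhomology = L,
          mechanism = "slippage/tandem-dup", stringsAsFactors = FALSE)
        cursor <- tpos + span + 1L
      } else {
        # span on parent: deletion consumes L bases; insertion consumes none.
        # Right edit region: m matched bases + 1 mismatch guard.
        pos <- cursor + 1L # 1-based start of event site; cursor is left guard
        consumed <- if (kind == "deletion") L else 0L
        if (pos + consumed + m > n) stop("parent too short to host all specs disjointly")
        seg <- if (kind == "deletion") {
          P[pos:(pos + L - 1L)]
        } else {
          random_bases(L)
        }
        rf <- pos + consumed # 1-based start of right flank
        if (m > 0L) P[rf:(rf + m - 1L)] <- seg[seq_len(m)]
        if (P[rf + m] == seg[m + 1L]) P[rf + m] <- other_base(seg[m + 1L])
        if (P[pos - 1L] == seg[L]) P[pos - 1L] <- other_base(seg[L])
        truth[[i]] <- data.frame(
          kind = kind, parent_pos = pos - 1L, length = L,
          seq = paste(seg, collapse = ""), microhomology = m,
          mechanism = paste0(mech), stringsAsFactors = FALSE)
        cursor <- rf + m + 1L
      }
    }
    truth <- do.call(rbind, truth)
    parent_out <- paste(P, collapse = "")
    derived <- apply_indels(parent_out, truth)
    structure(list(parent = parent_out, derived = derived, truth = truth),
              class = "planted_indels")
  })
}

#' Apply indel records to a parent sequence
#'
#' Reconstructs the derived (copy) sequence from the parent and a table of
#' indel records, the round-trip counterpart of indel extraction.
#'
#' @param parent Ungapped DNA string.
#' @param records data.frame with `kind`, `parent_pos` (0-based), `length`,
#'   and `seq` (the inserted segment, required for insertions). Events must
#'   not overlap.
#' @return The derived DNA string.
#' @export
apply_indels <- function(parent, records) {
  P <- chars(parent)
  if (nrow(records) == 0L) return(parent)
  ord <- order(records$parent_pos)
  records <- records[ord, , drop = FALSE]
  out <- character(0)
  cursor <- 0L # 0-based: bases [0, cursor) already emitted
  for (i in seq_len(nrow(records))) {
    pos <- records$parent_pos[i]
    L <- records$length[i]
    if (pos < cursor) stop("overlapping indel records")
    if (pos > cursor) out <- c(out, P[(cursor + 1L):pos])
    if (records$kind[i] == "deletion") {
      if (pos + L > length(P)) stop("deletion extends past parent end")
      cursor <- pos + L
    } else {
      out <- c(out, chars(records$seq[i]))
      cursor <- pos
    }
  }
  if (cursor < length(P)) out <- c(out, P[(cursor + 1L):length(P)])
  paste(out, collapse = "")
}

#' Render a planted parent/copy pair as a gapped pairwise alignment
#'
#' Builds the two-row alignment an aligner would produce from the planted
#' events. With `gap_placement = "random"` each gap is shifted right within
#' its microhomology tract (the placements a real aligner chooses among
#' arbitrarily), so downstream extraction must left-normalize to recover the
#' planted truth.
#'
#' @param planted A [plant_duplicate_indels()] result.
#' @param gap_placement `"left"` for canonical placement, `"random"` to shift
#'   each gap uniformly within its equivalent placements.
#' @param copy_id Name for the derived sequence row.
#' @param seed Integer seed (used for `"random"` placement).
#' @return An `aligned_set` (see [read_alignment()]) with rows `parent` and
#'   `copy_id`.
#' @export
indel_alignment <- function(planted, gap_placement = c("left", "random"),
                            copy_id = "copy", seed = NULL) {
  stopifnot(inherits(planted, "planted_indels"))
  gap_placement <- match.arg(gap_placement)
  P <- chars(planted$parent)
  tr <- planted$truth[order(planted$truth$parent_pos), , drop = FALSE]
  with_seed(seed, {
    pg <- character(0) # parent row
    cg <- character(0) # copy row
    cursor <- 0L
    for (i in seq_len(nrow(tr))) {
      pos <- tr$parent_pos[i]
      L <- tr$length[i]
      k <- if (gap_placement == "random" && tr$microhomology[i] > 0L) {
        sample.int(tr$microhomology[i] + 1L, 1L) - 1L
      } else 0L
      seg <- chars(tr$seq[i])
      if (tr$kind[i] == "deletion") {
        match_to <- pos + k # exclusive, 0-based
        if (match_to > cursor) {
          pg <- c(pg, P[(cursor + 1L):match_to])
          cg <- c(cg, P[(cursor + 1L):match_to])
        }
        pg <- c(pg, P[(match_to + 1L):(match_to + L)])
        cg <- c(cg, rep("-", L))
        cursor <- match_to + L
      } else {
        match_to <- pos + k
        if (match_to > cursor) {
          pg <- c(pg, P[(cursor + 1L):match_to])
          cg <- c(cg, P[(cursor + 1L):match_to])
        }
        rot <- if (k %% L == 0L) seg else c(seg[(k + 1L):L], seg[seq_len(k)])
        pg <- c(pg, rep("-", L))
        cg <- c(cg, rot)
        cursor <- match_to
      }
    }
    if (cursor < length(P)) {
      pg <- c(pg, P[(cursor + 1L):length(P)])
      cg <- c(cg, P[(cursor + 1L):length(P)])
    }
    seqs <- c(paste(pg, collapse = ""), paste(cg, collapse = ""))
    names(seqs) <- c("parent", copy_id)
    aligned_set(seqs, parent_id = "parent")
  })
}
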