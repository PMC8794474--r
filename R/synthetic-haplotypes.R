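# Haplotype matrices with known mutation and gene-conversion truth.
#
# The genealogy is a fixed two-clade ladder topology rather than a full
# coalescent: haplotypes split into two clades, mutations fall on the root
# branch (clade-diagnostic sites) or on nested "ladder" branches within a
# clade. Under this tree, any two sites are compatible (at most three gametes),
# so without conversion Rmin is 0 by construction; a conversion event copying a
# tract across clades creates four-gamete incompatibilities.

#' Simulate haplotypes with known gene-conversion events
#'
#' Generates an `n_hap x n_sites` binary haplotype matrix under infinite
#' sites on a fixed two-clade ladder genealogy, then applies
#' `n_conversion_events` gene-conversion events, each copying a tract of
#' `tract_len` bp from a donor in one clade into a recipient in the other.
#' Tract placement is retried until the event is guaranteed (from the truth
#' structure alone) to create a four-gamete incompatibility: the tract covers
#' a clade-diagnostic site while a ladder site carried by the recipient but
#' not by the whole clade lies outside the tract.
#'
#' @param n_hap Number of haplotypes (>= 5 when planting conversion events, so
#'   the recipient clade holds the two extra carriers the four-gamete pattern
#'   needs; >= 2 otherwise).
#' @param n_sites Number of segregating sites (>= 1).
#' @param seed Integer seed.
#' @param n_conversion_events Number of conversion events to plant.
#' @param tract_len Conversion tract length in bp.
#' @param seq_len Length of the underlying sequence; site positions are drawn
#'   without replacement from `1:seq_len`.
#' @param p_diagnostic Fraction of sites expected on the root (clade-splitting)
#'   branch.
#'
#' @return List with `matrix` (0/1, rows = haplotypes `hap1..`), `positions`
#'   (strictly increasing, 1-based), `events` (data.frame `donor`,
#'   `recipient`, `tract_start`, `tract_end`) and `site_edge` (the branch each
#'   mutation fell on, for truth bookkeeping).
#' @export
simulate_haplotypes <- function(n_hap, n_sites, seed = NULL,
                                n_conversion_events = 0, tract_len = 100,
                                seq_len = max(10L * n_sites, 1000L),
                                p_diagnostic = 0.3) {
  if (n_hap < 2L) stop("n_hap must be >= 2")
  if (n_sites < 1L) stop("n_sites must be >= 1")
  if (n_conversion_events > 0 && n_hap < 5L) {
    stop("planting conversion events needs n_hap >= 5 (recipient clade >= 3)")
  }
  if (seq_len < n_sites) stop("seq_len must be >= n_sites")
  with_seed(seed, {
    k <- n_hap %/% 2L
    clade1 <- seq_len(k)
    clade2 <- (k + 1L):n_hap
    # Branches: root (carriers = clade1) and ladders {1..j} within each clade.
    edges <- list(root = clade1)
    if (k > 1L) for (j in seq_len(k - 1L)) {
      edges[[paste0("c1_", j)]] <- clade1[seq_len(j)]
    }
    if (n_hap - k > 1L) for (j in seq_len(n_hap - k - 1L)) {
      edges[[paste0("c2_", j)]] <- clade2[seq_len(j)]
    }
    positions <- sort(sample.int(seq_len, n_sites))
    ladder_ids <- setdiff(names(edges), "root")
    pr <- c(p_diagnostic, rep((1 - p_diagnostic) / max(length(ladder_ids), 1L),
                              length(ladder_ids)))
    site_edge <- sample(names(edges), n_sites, replace = TRUE, prob = pr)
    H <- matrix(0L, n_hap, n_sites,
                dimnames = list(paste0("hap", seq_len(n_hap)), NULL))
    for (s in seq_len(n_sites)) H[edges[[site_edge[s]]], s] <- 1L
    events <- data.frame(donor = integer(0), recipient = integer(0),
                         tract_start = integer(0), tract_end = integer(0))
    if (n_conversion_events > 0) {
      diag_sites <- which(site_edge == "root")
      if (length(diag_sites) == 0L) {
        # force one diagnostic site so events can be planted
        s <- sample.int(n_sites, 1L)
        site_edge[s] <- "root"
        H[, s] <- 0L; H[clade1, s] <- 1L
        diag_sites <- s
      }
      for (e in seq_len(n_conversion_events)) {
        placed <- FALSE
        for (try in seq_len(200L)) {
          target <- sample(diag_sites, 1L)
          start <- max(1L, positions[target] - sample.int(tract_len, 1L) + 1L)
          end <- min(seq_len, start + tract_len - 1L)
          in_tract <- positions >= start & positions <= end
          donor <- if (k == 1L) 1L else sample(clade1, 1L)
          recipient <- if (n_hap - k == 1L) clade2 else sample(clade2, 1L)
          # witness: clade2 ladder site outside the tract carried by the
          # recipient plus at least one other clade2 haplotype (the 01
          # gamete), but not by every clade2 haplotype (the 00 gamete)
          witness <- vapply(seq_len(n_sites), function(s) {
            if (in_tract[s] || !startsWith(site_edge[s], "c2_")) return(FALSE)
            carriers <- edges[[site_edge[s]]]
            recipient %in% carriers && length(carriers) >= 2L &&
              length(carriers) < (n_hap - k)
          }, logical(1))
          if (in_tract[target] && any(witness)) {
            H[recipient, in_tract] <- H[donor, in_tract]
            events <- rbind(events, data.frame(
              donor = donor, recipient = recipient,
              tract_start = start, tract_end = end))
            placed <- TRUE
            break
          }
        }
        if (!placed) stop("could not place a guaranteed-detectable conversion ",
                          "event; increase n_sites or tract_len")
      }
    }
    list(matrix = H, positions = positions, events = events,
         site_edge = site_edge)
  })
}

#' Realize a haplotype matrix as gapped sequences
#'
#' Renders a simulated haplotype matrix as an alignment: a random ancestral
#' sequence over the full coordinate span, with each segregating site realized
#' either as a SNP (derived base differs from ancestral) or, for a fraction of
#' sites, as a short deletion (presence/absence), so that indel polymorphisms
#' participate as characters downstream.
#'
#' @param hm A [simulate_haplotypes()] result.
#' @param indel_fraction Fraction of sites realized as 3-bp deletions in
#'   derived-allele carriers instead of SNPs.
#' @param gc GC fraction of the ancestral sequence.
#' @param seed Integer seed.
#' @return An `aligned_set` of the haplotype sequences (no parent row), with
#'   attribute `site_type` (`"snp"`/`"indel"` per site).
#' @export
realize_haplotype_sequences <- function(hm, indel_fraction = 0.2, gc = 0.42,
                                        seed = NULL) {
  with_seed(seed, {
    n_sites <- length(hm$positions)
    len <- max(hm$positions) + 10L
    anc <- random_bases(len, gc)
    site_type <- ifelse(stats::runif(n_sites) < indel_fraction, "indel", "snp")
    # keep indel sites >= 4 bp apart from the next site so deletions stay
    # separate events
    if (n_sites > 1L) {
      gap_next <- c(diff(hm$positions), Inf)
      site_type[site_type == "indel" & gap_next < 4] <- "snp"
    }
    derived <- vapply(seq_len(n_sites), function(s) {
      if (site_type[s] == "snp") other_base(anc[hm$positions[s]]) else ""
    }, character(1))
    seqs <- apply(hm$matrix, 1L, function(g) {
      x <- anc
      for (s in seq_len(n_sites)) {
        p <- hm$positions[s]
        if (g[s] == 1L) {
          if (site_type[s] == "snp") x[p] <- derived[s]
          else x[p:min(p + 2L, len)] <- "-"
        }
      }
      paste(x, collapse = "")
    })
    out <- aligned_set(seqs, parent_id = NULL)
    attr(out, "site_type") <- site_type
    out
  })
}
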