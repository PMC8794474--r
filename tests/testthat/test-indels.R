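# Alignment parsing, indel extraction, microhomology and mechanism calls.

test_that("alignment reader validates and normalizes input", {
  path <- tempfile(fileext = ".fa")
  writeLines(c(">parent", "ac-gt", ">copy", "ACAGT"), path)
  aln <- read_alignment(path, parent_id = "parent")
  expect_equal(unname(aln$seqs["parent"]), "AC-GT") # upcased
  writeLines(c(">parent", "ACGT", ">copy", "ACG"), path)
  expect_error(read_alignment(path, parent_id = "parent"), "ragged")
  writeLines(c(">a", "ACGT", ">b", "ACQT"), path)
  expect_error(read_alignment(path), "unknown characters")
  writeLines(c(">a", "ACGT", ">b", "ACGT"), path)
  expect_error(read_alignment(path, parent_id = "parent"), "not in alignment")
  writeLines(c(">a", "ACGT"), path)
  expect_error(read_alignment(path), ">= 2 sequences")
})

test_that("single-gap alignments yield the expected records", {
  aln <- aligned_set(c(parent = "AC-GT", copy = "ACAGT"), parent_id = "parent")
  rec <- extract_indels(aln)
  expect_equal(rec$kind, "insertion")
  expect_equal(rec$length, 1L)
  expect_equal(rec$parent_pos, 2L)
  expect_equal(rec$seq, "A")

  # terminal gap runs are alignment-end artifacts by default
  aln2 <- aligned_set(c(parent = "ACGTACGT", copy = "ACGT----"),
                      parent_id = "parent")
  expect_equal(nrow(extract_indels(aln2)), 0L)
  kept <- extract_indels(aln2, keep_terminal_gaps = TRUE)
  expect_equal(kept$kind, "deletion")
  expect_equal(kept$length, 4L)
})

test_that("extraction left-normalizes gaps placed anywhere in a repeat", {
  # deletion of CT from ACTCTCTG: placements at any repeat unit are one event
  parent <- "ACTCTCTG"
  for (gapped in c("A--CTCTG", "ACT--CTG", "ACTCT--G")) {
    aln <- aligned_set(c(parent = parent, copy = gapped), parent_id = "parent")
    rec <- extract_indels(aln)
    expect_equal(rec$parent_pos, 1L)
    expect_equal(rec$length, 2L)
    expect_equal(rec$seq, "CT")
  }
  # same for an insertion within the repeat: parent row has the gap, the
  # copy carries an extra CT at any placement
  for (ins in c("A--CTCTCTG", "ACT--CTCTG", "ACTCT--CTG", "ACTCTCT--G")) {
    aln <- aligned_set(c(parent = ins, copy = sub("--", "CT", ins, fixed = TRUE)),
                       parent_id = "parent")
    rec <- extract_indels(aln)
    expect_equal(rec$kind, "insertion")
    expect_equal(rec$parent_pos, 1L)
    expect_equal(rec$seq, "CT")
  }
})

test_that("round trip: extracted records reconstruct every copy exactly", {
  for (s in 1:15) {
    set.seed(s)
    sp <- random_indel_spec(4)
    p <- plant_duplicate_indels(random_dna(320), sp, seed = s)
    aln <- indel_alignment(p, "random", seed = s + 1)
    rec <- extract_indels(aln)
    expect_identical(apply_indels(p$parent, rec), ungap(aln$seqs[["copy"]]))
  }
})

test_that("microhomology is the max directional junction match", {
  # parent = AAGG|ATCC|ATGG: right flank of the ATCC deletion begins AT -> 2
  rec <- data.frame(kind = "deletion", parent_pos = 4L, length = 4L,
                    seq = "ATCC", stringsAsFactors = FALSE)
  expect_equal(measure_microhomology("AAGGATCCATGG", rec), 2L)

  # flanks share no junction identity -> 0
  rec0 <- data.frame(kind = "deletion", parent_pos = 4L, length = 2L,
                     seq = "TT", stringsAsFactors = FALSE)
  expect_equal(measure_microhomology("AAGGTTCCAAGG", rec0), 0L)

  # left-directional match counts too (suffix of deletion vs left flank):
  # parent CTAG|TAG|CCCC, deleting the second TAG: lcs(TAG, CTAG) = 3
  recL <- data.frame(kind = "deletion", parent_pos = 4L, length = 3L,
                     seq = "TAG", stringsAsFactors = FALSE)
  expect_equal(measure_microhomology("CTAGTAGCCCC", recL), 3L)

  expect_error(measure_microhomology("ACGT",
    data.frame(kind = "deletion", parent_pos = 2L, length = 5L, seq = "GTAAA")),
    "out of range")
})

test_that("planted microhomology 0..6 is recovered exactly", {
  for (m in 0:6) {
    specs <- data.frame(kind = c("deletion", "insertion"), length = 8L,
                        microhomology = m,
                        mechanism = if (m >= 2) "MMEJ-like" else "slippage")
    # m < 2 cannot be MMEJ-like at 8 bp; use 6 bp events instead
    if (m < 2) specs$length <- 6L
    specs$mechanism <- "MMEJ-like"
    set.seed(m + 40)
    p <- plant_duplicate_indels(random_dna(150), specs, seed = m)
    rec <- extract_indels(indel_alignment(p, "random", seed = m + 1))
    expect_equal(measure_microhomology(p$parent, rec), rep(m, 2L))
  }
})

test_that("mechanism classification follows slippage/size/microhomology rules", {
  # insertion ACG directly after ACG: tandem duplication
  recs <- data.frame(kind = "insertion", parent_pos = 7L, length = 3L,
                     seq = "ACG", microhomology = 3L, stringsAsFactors = FALSE)
  expect_equal(classify_mechanism("TTTTACGGGTT", recs), "slippage/tandem-dup")

  parent <- "TTTTTTTTTTTTTTTTTTTTTTTTTTTTGG"
  mk <- function(L, m, kind = "deletion", seq = strrep("A", L)) {
    data.frame(kind = kind, parent_pos = 2L, length = L, seq = seq,
               microhomology = m, stringsAsFactors = FALSE)
  }
  # 2 bp, m = 0: NHEJ-like (size rule)
  expect_equal(classify_mechanism("GGCATTGGCCGG", mk(2, 0, seq = "AT")), "NHEJ-like")
  # 12 bp deletion with m = 2: MMEJ-like
  set.seed(50)
  p <- plant_duplicate_indels(random_dna(120),
    data.frame(kind = "deletion", length = 12, microhomology = 2,
               mechanism = "MMEJ-like"), seed = 51)
  rec <- annotate_indels(p$parent, extract_indels(indel_alignment(p)))
  expect_equal(rec$mechanism, "MMEJ-like")
  # 5 bp event: MMEJ-like even without microhomology (size-only fallback)
  p5 <- plant_duplicate_indels(random_dna(120),
    data.frame(kind = "deletion", length = 5, microhomology = 0,
               mechanism = "MMEJ-like"), seed = 52)
  rec5 <- annotate_indels(p5$parent, extract_indels(indel_alignment(p5)))
  expect_equal(rec5$mechanism, "MMEJ-like")
  # > 7 bp with m < 2 stays unclassified
  rec_u <- data.frame(kind = "deletion", parent_pos = 10L, length = 10L,
                      seq = "GGGGGGGGGG", microhomology = 0L)
  long_parent <- paste0(strrep("ACT", 4), strrep("G", 10), "TCATCATCA")
  expect_equal(classify_mechanism(long_parent, rec_u), "unclassified")
})

test_that("sharing classification keys on gene, kind, position and length", {
  recs <- data.frame(
    gene = c("g1", "g1", "g1", "g1", "g2"),
    copy_id = c("sim_a", "mau_a", "sec_a", "sec_a", "solo"),
    kind = "deletion",
    parent_pos = c(10L, 10L, 25L, 10L, 5L),
    length = c(4L, 4L, 4L, 7L, 3L),
    stringsAsFactors = FALSE)
  species <- c(sim_a = "sim", mau_a = "mau", sec_a = "sec", solo = "mel")
  out <- classify_sharing(recs, species)
  expect_equal(out$sharing[1:2], c("shared", "shared"))
  expect_equal(out$sharing[3], "species-specific")
  # same position, different length: distinct, species-specific
  expect_equal(out$sharing[4], "species-specific")
  # single-species gene: NA
  expect_true(is.na(out$sharing[5]))
  expect_error(classify_sharing(recs, species[-1]), "without species")
})
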