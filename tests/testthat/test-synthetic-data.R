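# Generators: determinism, declared distributions, and planted ground truth.

test_that("simulate_genome builds the requested contigs deterministically", {
  g <- simulate_genome(c(Y = 1), length_range = c(10000, 10000), seed = 1)
  expect_equal(nrow(g$truth), 1L)
  expect_equal(g$truth$class, "Y")
  expect_equal(g$truth$length, 10000L)
  expect_equal(nchar(g$sequences), setNames(10000L, g$truth$contig))

  a <- simulate_genome(c(autosome = 2, X = 1, Y = 1), seed = 7)
  b <- simulate_genome(c(autosome = 2, X = 1, Y = 1), seed = 7)
  expect_identical(a, b)

  empty <- simulate_genome(c(Y = 0), seed = 1)
  expect_equal(nrow(empty$truth), 0L)

  expect_error(simulate_genome(c(Y = 1), length_range = c(500, 900), seed = 1),
               "10,000")
  expect_error(simulate_genome(c(W = 1), seed = 1), "named")
})

test_that("depth tracks follow the class- and sex-specific Poisson means", {
  g <- simulate_genome(c(autosome = 1, X = 1, Y = 1), seed = 2)
  dt <- simulate_depth_tracks(g, male_autosomal_cov = 50, mismap_rate = 0,
                              seed = 3)
  ctg <- setNames(g$truth$contig, g$truth$class)

  # mismap 0: female depth on Y identically zero
  expect_true(all(dt$female[[ctg["Y"]]] == 0L))

  # autosomal male mean within 3 SE of 50 (Poisson SE over >= 10 kb)
  n <- length(dt$male[[ctg["autosome"]]])
  se <- sqrt(50 / n)
  expect_lt(abs(mean(dt$male[[ctg["autosome"]]]) - 50), 3 * se)

  # X: female mean ~ 2x male mean
  fm <- mean(dt$female[[ctg["X"]]]) / mean(dt$male[[ctg["X"]]])
  expect_lt(abs(fm - 2), 0.15)

  # determinism
  expect_identical(dt, simulate_depth_tracks(g, 50, 0, seed = 3))
  expect_error(simulate_depth_tracks(g, -1, 0), "male_autosomal_cov")
  expect_error(simulate_depth_tracks(g, 50, 1), "mismap_rate")
})

test_that("exon depth simulator matches Poisson(base_cov * CN)", {
  ex <- data.frame(id = c("a", "b", "c"), length = c(10000, 500, 10000),
                   true_cn = c(1, 0, 4))
  sd <- simulate_exon_depths(ex, base_cov = 50, seed = 4)
  expect_equal(length(sd$depth), sum(ex$length))
  d_a <- sd$depth[(sd$features$start[1] + 1):sd$features$end[1]]
  d_b <- sd$depth[(sd$features$start[2] + 1):sd$features$end[2]]
  d_c <- sd$depth[(sd$features$start[3] + 1):sd$features$end[3]]
  expect_true(all(d_b == 0L))
  expect_lt(abs(mean(d_a) - 50), 3 * sqrt(50 / length(d_a)))
  expect_lt(abs(mean(d_c) - 200), 3 * sqrt(200 / length(d_c)))
  # modal depth of the CN=1 sites is the single-copy coverage
  expect_lt(abs(modal_depth(d_a) - 50), 3)
})

test_that("plant_duplicate_indels round-trips and plants exact truth", {
  # empty specs: identity
  empty <- data.frame(kind = character(0), length = integer(0),
                      microhomology = integer(0), mechanism = character(0))
  p0 <- plant_duplicate_indels(strrep("ACGT", 20), empty, seed = 1)
  expect_identical(p0$derived, p0$parent)
  expect_equal(nrow(p0$truth), 0L)

  # planted microhomology is what the measuring code reports (12 bp, m = 2)
  specs <- data.frame(kind = "deletion", length = 12, microhomology = 2,
                      mechanism = "MMEJ-like")
  set.seed(5)
  p <- plant_duplicate_indels(random_dna(120), specs, seed = 6)
  expect_equal(measure_microhomology(p$parent, p$truth), 2L)
  expect_identical(apply_indels(p$parent, p$truth), p$derived)

  # slippage insertion duplicates the left-adjacent parent segment
  sl <- data.frame(kind = "insertion", length = 3, microhomology = 3,
                   mechanism = "slippage")
  set.seed(7)
  ps <- plant_duplicate_indels(random_dna(80), sl, seed = 8)
  P <- strsplit(ps$parent, "")[[1]]
  pos <- ps$truth$parent_pos
  expect_identical(paste(P[(pos + 1):(pos + 3)], collapse = ""), ps$truth$seq)

  # round trip + determinism across random specs
  for (s in 1:10) {
    set.seed(s)
    sp <- random_indel_spec(3)
    parent <- random_dna(250)
    pl <- plant_duplicate_indels(parent, sp, seed = s + 100)
    expect_identical(apply_indels(pl$parent, pl$truth), pl$derived)
    expect_identical(pl, plant_duplicate_indels(parent, sp, seed = s + 100))
  }
})

test_that("indel spec validation rejects inconsistent mechanisms", {
  bad1 <- data.frame(kind = "deletion", length = 5, microhomology = 5,
                     mechanism = "MMEJ-like") # m == L is slippage
  expect_error(plant_duplicate_indels(strrep("ACGT", 30), bad1), "slippage")
  bad2 <- data.frame(kind = "deletion", length = 6, microhomology = 0,
                     mechanism = "NHEJ-like")
  expect_error(plant_duplicate_indels(strrep("ACGT", 30), bad2), "1-3 bp")
  bad3 <- data.frame(kind = "deletion", length = 12, microhomology = 1,
                     mechanism = "MMEJ-like")
  expect_error(plant_duplicate_indels(strrep("ACGT", 30), bad3), "MMEJ")
  # parent too short
  big <- data.frame(kind = "deletion", length = 50, microhomology = 2,
                    mechanism = "MMEJ-like")
  expect_error(plant_duplicate_indels("ACGTACGTAC", big), "too short")
})

test_that("fixture VCF realizes requested allele frequencies exactly", {
  path <- tempfile(fileext = ".vcf")
  recs <- data.frame(chrom = "2L", pos = 100, ref = "ATT", alt = "A",
                     af = 0.2, missing = 0)
  write_fixture_vcf(10, recs, path, seed = 1)
  lines <- readLines(path)
  gt <- strsplit(lines[length(lines)], "\t")[[1]][-(1:9)]
  expect_equal(sum(gt == "1"), 2L)
  expect_equal(sum(gt == "0"), 8L)

  # header-only VCF parses to zero records
  write_fixture_vcf(4, recs[0, ], path, seed = 1)
  expect_equal(nrow(filter_vcf_indels(path, maf = 0)), 0L)

  # impossible frequency/missingness combination rejected
  bad <- data.frame(chrom = "2L", pos = 1, ref = "AT", alt = "A",
                    af = 0.15, missing = 0)
  expect_error(write_fixture_vcf(10, bad, path, seed = 1), "not realizable")
})

test_that("haplotype simulator is deterministic and infinite-sites clean", {
  a <- simulate_haplotypes(8, 30, seed = 9)
  b <- simulate_haplotypes(8, 30, seed = 9)
  expect_identical(a, b)
  expect_true(is.unsorted(a$positions) == FALSE)
  # no conversion: tree-compatible, so no four-gamete pair and rmin 0
  expect_equal(nrow(four_gamete_pairs(a)), 0L)
  expect_equal(rmin(a), 0L)
  expect_error(simulate_haplotypes(1, 5), "n_hap")
  expect_error(simulate_haplotypes(4, 5, n_conversion_events = 1), "n_hap >= 5")
})
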