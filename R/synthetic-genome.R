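#' Simulate a labeled genome assembly
#'
#' Generates random contigs with known chromosome class, standing in for an
#' assembly whose windows have known chromosomal locations. Classes follow the
#' Drosophila karyotype used throughout the package: `autosome`, `X`, `Y` and
#' `dot` (the small heterochromatic fourth chromosome).
#'
#' @param n_per_class Named integer vector (or list) giving the number of
#'   contigs per class; names must be a subset of
#'   `c("autosome", "X", "Y", "dot")`. Classes may be omitted or zero.
#' @param length_range Length-2 numeric, the (min, max) contig length in bp.
#'   Minimum allowed is 10,000 bp so that every contig holds at least one full
#'   10-kb assignment window.
#' @param gc GC fraction of the simulated sequence.
#' @param seed Integer seed; fixed seed gives byte-identical output.
#'
#' @return An object of class `labeled_genome`: a list with
#'   \describe{
#'     \item{sequences}{named character vector of DNA sequences}
#'     \item{truth}{data.frame with columns `contig`, `class`, `length`}
#'   }
#' @export
#'
#' @examples
#' g <- simulate_genome(c(autosome = 2, Y = 1), seed = 1)
#' g$truth
simulate_genome <- function(n_per_class,
                            length_range = c(10000, 20000),
                            gc = 0.42,
                            seed = NULL) {
  n_per_class <- unlist(n_per_class)
  classes <- c("autosome", "X", "Y", "dot")
  if (is.null(names(n_per_class)) || !all(names(n_per_class) %in% classes)) {
    stop("`n_per_class` must be named with classes among: ",
         paste(classes, collapse = ", "))
  }
  if (any(n_per_class < 0)) stop("contig counts must be >= 0")
  if (length(length_range) != 2L || any(length_range < 10000)) {
    stop("contig lengths must be >= 10,000 bp (one full assignment window)")
  }
  with_seed(seed, {
    cls <- rep(names(n_per_class), times = n_per_class)
    n <- length(cls)
    truth <- data.frame(
      contig = if (n) sprintf("ctg%03d_%s", seq_len(n), cls) else character(0),
      class = cls,
      length = if (n) {
        as.integer(round(stats::runif(n, length_range[1], length_range[2])))
      } else integer(0),
      stringsAsFactors = FALSE
    )
    seqs <- vapply(truth$length, random_dna, character(1), gc = gc)
    names(seqs) <- truth$contig
    structure(list(sequences = seqs, truth = truth), class = "labeled_genome")
  })
}

# Poisson depth means per class for each sex. C is the male autosomal
# coverage; the Y is hemizygous (C/2) in males and absent in females except
# for a uniform mismapping "leak"; the X is C/2 in males and C in females.
depth_mean_for_class <- function(class, sex, C, mismap_rate) {
  male <- c(autosome = C, X = C / 2, Y = C / 2, dot = C)
  female <- c(autosome = C, X = C, Y = C * mismap_rate, dot = C)
  if (sex == "male") unname(male[class]) else unname(female[class])
}

#' Simulate male and female per-base depth tracks
#'
#' Per-base read depth is Poisson with a class- and sex-specific mean,
#' emulating a male/female coverage assay over the same assembly: autosomes
#' and the dot chromosome have full coverage `C` in both sexes, the X has
#' `C/2` in males and `C` in females, and the Y has `C/2` in males and
#' `C * mismap_rate` in females. The female-on-Y "leak" models reads from
#' repetitive sequence mismapping onto Y contigs.
#'
#' @param genome A [simulate_genome()] result.
#' @param male_autosomal_cov Male autosomal coverage `C` (> 0).
#' @param mismap_rate Fraction in `[0, 1)`: mean female depth on Y contigs as
#'   a fraction of `C`.
#' @param seed Integer seed.
#'
#' @return List with elements `male` and `female` (each a named list of
#'   integer depth vectors, one per contig; a `depth_track`) and `truth`
#'   (the genome's truth table).
#' @export
simulate_depth_tracks <- function(genome,
                                  male_autosomal_cov = 50,
                                  mismap_rate = 0,
                                  seed = NULL) {
  stopifnot(inherits(genome, "labeled_genome"))
  if (male_autosomal_cov <= 0) stop("male_autosomal_cov must be > 0")
  if (mismap_rate < 0 || mismap_rate >= 1) stop("mismap_rate must be in [0, 1)")
  with_seed(seed, {
    tr <- genome$truth
    one_sex <- function(sex) {
      out <- lapply(seq_len(nrow(tr)), function(i) {
        mu <- depth_mean_for_class(tr$class[i], sex, male_autosomal_cov,
                                   mismap_rate)
        if (mu == 0) integer(tr$length[i]) else rpois(tr$length[i], mu)
      })
      names(out) <- tr$contig
      out
    }
    list(male = one_sex("male"), female = one_sex("female"), truth = tr)
  })
}

#' Simulate exon depth with known integer copy number
#'
#' Places exons end-to-end on a concatenated transcript coordinate system and
#' draws per-site depth from `Poisson(base_cov * true_cn)`, emulating reads
#' mapped to a transcript reference where duplicated exons accumulate
#' proportionally more depth.
#'
#' @param exons data.frame with columns `id`, `length` (bp) and `true_cn`
#'   (integer >= 0).
#' @param base_cov Single-copy coverage (> 0).
#' @param seed Integer seed.
#'
#' @return List with `depth` (integer vector over the concatenated
#'   transcript), `features` (data.frame `id`, `start`, `end`, 0-based
#'   half-open) and `truth` (the input exon table).
#' @export
simulate_exon_depths <- function(exons, base_cov = 50, seed = NULL) {
  stopifnot(is.data.frame(exons),
            all(c("id", "length", "true_cn") %in% names(exons)))
  if (any(exons$true_cn < 0)) stop("true_cn must be >= 0")
  if (base_cov <= 0) stop("base_cov must be > 0")
  with_seed(seed, {
    ends <- cumsum(exons$length)
    starts <- c(0L, ends[-length(ends)])
    depth <- unlist(lapply(seq_len(nrow(exons)), function(i) {
      mu <- base_cov * exons$true_cn[i]
      if (mu == 0) integer(exons$length[i]) else rpois(exons$length[i], mu)
    }), use.names = FALSE)
    list(
      depth = depth,
      features = data.frame(id = exons$id, start = starts, end = ends,
                            stringsAsFactors = FALSE),
      truth = exons
    )
  })
}
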