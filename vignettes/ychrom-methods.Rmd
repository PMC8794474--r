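---
title: "Methods: coverage-based Y-linkage, repair signatures, copy number and gene-conversion bounds"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: coverage-based Y-linkage, repair signatures, copy number and gene-conversion bounds}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ychrom)
```

`ychrom` implements four analyses used to study the structural evolution of
*Drosophila* Y chromosomes, together with a synthetic-data generator that
produces every input with known ground truth. This vignette is the package's
account of the underlying models, the tunable parameters, the numerical
choices, and what validation on synthetic data does and does not establish.

## 1. Y-linkage assignment from male vs female depth

**Model.** The Y chromosome is hemizygous and male-limited: in a male
short-read library, Y contigs receive about half the autosomal coverage `C`
(as does the X); in a female library, Y contigs receive essentially zero
uniquely mapped coverage while the X receives full coverage. Per-base depth
is treated as Poisson with these class-specific means. Female reads observed
on true Y sequence come from mismapping off repetitive elements shared with
other chromosomes; the simulator models this as a uniform Poisson "leak" with
mean `C * mismap_rate` (`simulate_depth_tracks()`).

**Procedure.** `window_stats()` summarizes 10-kb windows (0-based half-open;
a trailing partial window shorter than half a span is merged into its
neighbor, otherwise kept). The discriminating statistic is the median of
per-site `female/male` depth ratios over sites with male depth > 0; sites
with zero male depth are uninformative about the ratio and excluded, and
windows with no informative site are called `ambiguous`. The strict
"median female/male coverage equals zero" rule is the limit `fm_max = 0` of
the window classifier; the default tolerance `fm_max = 0.1` accommodates the
mismapping leak, mirroring the whole-contig female-to-male read-ratio
criterion (`< 0.1`) that is available as an additional contig-level filter
(`classify_contigs(extra_criterion = TRUE)`). That extra criterion exists for
datasets where male and female libraries differ in construction, which
inflates the false-positive rate of the window rule alone.

Two readings of "median of male-to-female coverage" are possible — the median
of per-site ratios, or a ratio of medians. The per-site-ratio median is the
default here because it is defined whenever any site has male coverage and it
is robust to a handful of high-coverage repeat sites; the window medians
needed for the other reading are reported in the same table, so either rule
can be applied.

**Parameters.** `fm_max` (unitless ratio, default 0.1), `min_male_depth`
(reads, default 5 — below this the window carries too little male signal to
distinguish Y-linked from unmappable sequence and is called ambiguous rather
than non-Y), `window` (bp, default 10,000), `fm_reads_max` (default 0.1).
Library-size differences are handled by `normalize_libraries()`, which scales
the female track by the ratio of male to female median autosomal depth; the
simulator draws both sexes at the same `C`, so the rescale factor is ~1
there.

**What the simulation does not emulate.** Real mismapping is not uniform: it
concentrates on specific repeat families, so real false positives are
clustered, and real libraries differ in insert size and bias. Passing the
synthetic recovery checks (sensitivity ≥ 0.95, FPR ≤ 0.05 at 2% leak, and
perfect recovery with no leak) demonstrates the statistical machinery, not
performance on any particular assembly.

## 2. Indel repair signatures

**Model.** Y chromosomes lack a homolog and must repair double-strand breaks
by non-homologous end joining (NHEJ), which typically leaves small (1–3 bp)
indels, or microhomology-mediated end joining (MMEJ), which anneals at short
(≥ 2 bp) identical stretches and produces larger deletions and tandem
duplications. Indels between a Y-linked duplicate and its parent gene
therefore carry a mechanistic signature in their size and junction
microhomology.

**Extraction.** `extract_indels()` takes each copy/parent pairwise projection
of the alignment, treats maximal gap runs in the copy as deletions and in the
parent as insertions, drops columns gapped in both, and excludes terminal gap
runs by default (they are usually truncation artifacts;
`keep_terminal_gaps = TRUE` restores them). Every event is left-normalized —
shifted to its leftmost equivalent placement — so records are invariant to
where the aligner happened to put the gap inside a repeat or microhomology
tract. The round-trip invariant (parent + records reconstructs the copy
exactly) is tested property-style.

**Microhomology.** For a deletion of segment `D` with flanks `L | D | R`,
`measure_microhomology()` returns
`max(lcp(D, R), lcs(D, L))`, capped at `length(D)` (`lcp`/`lcs` = longest
common prefix/suffix); insertions use the inserted segment against the same
flanks. The maximum of the two directional matches — not their sum — is used
because a single MMEJ junction anneals at one microhomology, and the cap
keeps `0 ≤ m ≤ length` testable.

**Mechanism rules** (`classify_mechanism()`): events whose segment exactly
equals an adjacent parent segment of the same length are
`slippage/tandem-dup`; otherwise 1–3 bp events are `NHEJ-like`; events of
4–7 bp are `MMEJ-like` on size alone; events > 7 bp are `MMEJ-like` only
with microhomology ≥ 2 bp and `unclassified` otherwise. Size bins for
spectra default to 1 / 2–3 / 4–6 / 7–9 / ≥ 10 bp, exposing the NHEJ size
range, the > 7 bp microhomology window, and the ≥ 10 bp "large deletion"
class whose relative frequency is the headline Y-vs-rest comparison
(`size_spectrum()`, `compare_large_deletion_fraction()`).

**Population indels.** `filter_vcf_indels()` reproduces the vcftools-style
filter: biallelic indels, minor allele frequency ≥ 0.1 computed from GT
calls over non-missing samples (never the `AF` INFO field), and a cap on
missing genotypes. `annotate_regions()` assigns each indel's 1-based VCF
position, converted to a 0-based point, to labeled BED regions
(intergenic/pseudogene) and to the chromosome partition autosome / X / dot.
Sharing of duplicate-gene indels across species uses exact identity —
(gene, kind, left-normalized position, length) — deliberately conservative
so near-identical events are never chained; `dedupe_indels()` optionally
collapses events repeated across copies of one gene.

**Planting truth.** The generator (`plant_duplicate_indels()`) edits flank
bases so the junction identity is *exactly* the requested `m`: the right
flank's first `m` bases are set to the segment's prefix, base `m + 1` is
forced to mismatch, and the base left of the event is forced to differ from
the segment's last base — which simultaneously zeroes the left-directional
match and makes the planted position the left-normalized one. Slippage
events copy an exact adjacent tandem segment and have `m = length` by
construction. Non-slippage specs require `m < length` because at equality
the event *is* a tandem duplication. `indel_alignment(gap_placement =
"random")` then re-renders the pair with each gap shifted uniformly within
its equivalence range, so extraction is tested against aligner-style
placement ambiguity, not against the generator's own canonical coordinates.

**Chi-square.** `chi_square()` computes the Pearson statistic and
`df = (r-1)(c-1)` in-package and takes the upper-tail probability from the
chi-square distribution. Tests compare it against a 200,000-draw fixed-margin
permutation oracle (via `r2dtable`) on five tables chosen with counts large
enough that the asymptotic and the discrete conditional null agree within
three Monte-Carlo standard errors; for very small tables the two genuinely
differ, which is a property of the asymptotic test, not a defect of the
implementation.

## 3. Exon copy number

Most Y-linked exons are single copy, so the mode of the integer depth
histogram across all Y-linked transcript sites estimates the one-copy depth
("the majority of depth"); `modal_depth()` breaks ties toward the smaller
depth and considers only positive depths, since zero-depth sites reflect
absent sequence, not a coverage level. Per-site copy number is
`depth / modal`; `estimate_exon_cn()` summarizes each exon by the median
(robust to exon-boundary edge effects; the mean is reported alongside) and
rounds to the nearest non-negative integer. Zero-depth exons yield copy
number 0 — a deletion call, not an error. Copy-number estimates are scale
invariant by construction. `compare_profiles()` flags exons whose estimates
differ by ≥ 1 copy between two profiles — the signature of a duplicate
present in reads but collapsed in an assembly. On Poisson 50x simulations
with true copy number in {0, 1, 2, 4} and exons ≥ 200 bp, rounded estimates
recover truth for ≥ 95% of exons (in practice ~100%); real depth adds GC
bias and mappability structure the simulation does not model, and no GC
correction is applied.

## 4. Gene-conversion bounds

Among near-identical ampliconic gene copies, crossing over is absent but
gene conversion homogenizes paralogs. Under infinite sites on a single tree,
any two biallelic sites show at most three of the four gametes 00/01/10/11;
a pair showing all four (`four_gamete_pairs()`) implies a recombination or
conversion breakpoint strictly between the sites. `rmin()` computes the
Hudson–Kaplan lower bound: incompatible pairs become open intervals, and the
maximum number of pairwise-disjoint intervals — greedy by right endpoint,
which is provably optimal for interval packing — is the minimum number of
events. Haplotypes missing at either site of a pair are excluded from that
pair's gamete count (pairwise-complete treatment). `encode_alignment()`
builds the site matrix from an alignment, including each distinct
left-placed gap run as one presence/absence character (indel polymorphisms
increase the usable site count substantially in short, highly similar
copies); columns are polarized by major allele with ties broken toward the
allele seen first, a convention that leaves four-gamete status and Rmin
unchanged. Per-generation conversion rates are deliberately not derived:
converting Rmin into a rate requires population-genetic assumptions (copy
number history, effective size, tract length distribution) that the data do
not pin down, so the module reports Rmin, Rmin per kb, the incompatible-pair
count, and mean pairwise identity.

**Simulator.** `simulate_haplotypes()` uses a fixed two-clade ladder
genealogy rather than a coalescent: mutations fall on the root branch
(clade-diagnostic sites, ~30% by default) or nested ladder branches. This is
sufficient to create and destroy four-gamete incompatibilities with known
truth while keeping the module desk-scale; it does not model recombination
graph complexity or realistic site-frequency spectra. Conversion events copy
a tract (default 100 bp here, 60 bp in the test conditions) from a donor in
one clade into a recipient in the other; tract placement is retried until
the truth structure alone guarantees a detectable incompatibility (tract
covers a diagnostic site; a ladder site carried by the recipient and at
least one other, but not all, clade members lies outside the tract), which
requires at least five haplotypes. Each planted tract has two breakpoints,
so Rmin is checked against the bound `1 ≤ Rmin ≤ 2k` for `k` events.

## Problem sizes and validation scale

The packaged validation (tests and `scripts/acceptance.R`) runs at sizes
chosen to exercise every code path while completing in about a minute per
module on one CPU: 20 contigs of 10–20 kb for the classifier, 1,000 planted
indels across 250 fixtures, 500 random 8×10 haplotype matrices against
exhaustive oracles, 100 copy-number replicates of 15 exons, and 200,000
permutation draws per chi-square table. These sizes give Monte-Carlo
standard errors comfortably inside the asserted tolerances; all thresholds
(3 SE for distributional checks, exactness for planted-truth recovery) were
fixed by the study conditions, not tuned to outcomes.

## Known limitations

- The uniform mismapping leak is a stand-in; real female coverage on Y
  contigs tracks specific repeat families.
- Mechanism classification is heuristic: NHEJ can occasionally produce
  large indels and MMEJ small ones, so per-event calls are evidence classes,
  not ground truth; only planted events have exact expected labels.
- The 223-indel-scale duplicate analysis depends on upstream multiple
  alignments; alignment errors masquerade as indels and are out of scope.
- Rmin is a lower bound and badly underestimates event counts when tracts
  overlap or recur at the same sites.
- No GC-bias or mappability correction in copy-number estimation.
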