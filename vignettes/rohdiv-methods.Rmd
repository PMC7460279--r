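---
title: "Methods: runs of homozygosity, genomic inbreeding and population structure in rohdiv"
author: "rohdiv authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: runs of homozygosity, genomic inbreeding and population structure in rohdiv}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`rohdiv` implements the standard genome-wide diversity workflow for
multi-breed SNP-array surveys of livestock — quality control, per-breed
diversity indices, runs of homozygosity (ROH) with genomic inbreeding,
autozygosity islands, and distance-based population structure — together
with a seeded synthetic-genotype generator that makes every stage testable
against known truth. This vignette documents the models, the parameter
conventions and the design decisions; it states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` themselves
compute.

## Data model

A `GenotypeDataset` extends `RangedSummarizedExperiment`: rows are
biallelic SNP markers (a `GRanges` on autosomes 1–28 carrying the marker
id and the two allele symbols), columns are samples with breed labels, and
the single `calls` assay holds integer codes 0 (homozygous for allele A),
1 (heterozygous), 2 (homozygous for allele B), `NA` (missing). Markers are
kept sorted by chromosome and 1-based physical position, positions
strictly increasing — every downstream coordinate convention (ROH spans,
island lengths) inherits this 1-based, closed-interval representation.

PED/MAP input follows the de-facto array exchange format: the PED family
column carries the breed label, and allele A of each marker is defined as
the first allele observed in file order. This makes the coding
deterministic at the cost of not round-tripping the allele orientation:
re-reading a written PED may complement codes at markers whose first
listed genotype is the opposite homozygote, which leaves every genotype,
frequency and downstream statistic unchanged (the test suite checks this
equivalence explicitly). Markers observed with a single allele keep a
`"0"` placeholder as allele B, since PED cannot name an unobserved allele.
Half-calls (one allele missing) are conservatively treated as missing,
with a warning.

## Quality control

Three filters are applied in a fixed, reported order: (1) samples with
more than 10% missing genotypes; (2) markers with call rate below 95%,
computed on the surviving samples; (3) markers with pooled minor allele
frequency below 5%. Items exactly at a threshold are kept, matching the
strict-inequality phrasing of the usual filter description. The order
samples → call rate → MAF was chosen so that marker statistics reflect the
cohort actually analysed; it is recorded in the `QCReport` because the
order is a genuine free choice that changes the surviving marker set. MAF
is pooled across all samples rather than per breed, since the filter is
applied once to a combined multi-breed dataset.

## Diversity indices

Per breed, the package reports the mean and SD across markers of the
within-breed minor allele frequency, the observed heterozygote fraction
Ho, and the Hardy–Weinberg expectation He = 2p(1−p); markers with no
non-missing call in the breed are excluded. For MAF/Ho/He the SD is the
population SD across markers; for the inbreeding coefficient it is the
sample SD across individuals — the two axes the respective magnitudes are
usually quoted on.

The excess-homozygosity inbreeding coefficient for individual *i* is

F_i = (O_i − E_i) / (L_i − E_i),

with O_i the observed homozygote count over the L_i markers typed in *i*
and E_i = Σ_j (1 − 2 p_j q_j c_j) the expected count under HWE;
c_j = 2n_j/(2n_j − 1) is the small-sample correction with n_j the
non-missing cohort size at marker j. Two conventions are deliberately
exposed as arguments rather than guessed silently:

* `freqScope` — expectations from the individual's own breed (default) or
  from the pooled dataset. The within-breed default is the only choice
  under which commercial outbred stocks can show the small negative
  F values that accompany He < Ho within their own cohort; the global
  scope instead measures deviation from the pooled panel and is kept for
  sensitivity checks.
* `correction` — the 2n/(2n−1) factor (default on, the convention of the
  common genotype-analysis tools). With the correction off and complete
  genotypes, mean F in an HWE cohort tends to 0 as n grows; the test suite
  verifies this by simulation.

## ROH detection

A run must satisfy five constraints: at least 100 SNPs and 1000 kb; at
most 1 heterozygous and 2 missing calls; average density of at least one
SNP per 100 kb; and no gap above 1000 kb between consecutive SNPs. All
five are `ROHParams` fields.

Two calling modes exist because the classic tooling words the limits at
run level but implements a windowed heuristic:

* **segment mode** (default, the canonical semantics): the caller emits
  the greedy longest-first selection of non-overlapping windows among
  *all* index ranges satisfying the five constraints, ties broken by the
  leftmost start. This is deterministic, testable, and exactly equal to a
  brute-force enumerator that scores every index pair and applies the same
  selection — an equivalence the acceptance suite checks on 200 random
  chromosomes. The implementation (C++) splits each chromosome at
  oversized gaps, finds the longest feasible window in each free range via
  a two-pointer sweep with a density back-scan, and recurses left and
  right of every selection.
* **window mode**: sliding windows of `windowSnps` (default 50) SNPs are
  scored homozygous when within the het/missing allowances; a SNP is
  in-run when at least `windowHitThreshold` (default 0.05) of its covering
  windows are homozygous; maximal in-run stretches are split at oversized
  gaps and then filtered by the five run-level constraints. The window
  parameters are the defaults of the original heuristic and are surfaced
  as parameters because they are conventions, not published values.

Run coordinates are the positions of the first and last SNP, and
`length_bp = end − start`. The end−start convention (rather than
end−start+1) is pinned by published chicken island tables whose printed
lengths equal exactly the difference of the printed start/end positions;
`scripts/acceptance.R` re-derives all four printed lengths through the
island code path.

A consequence of constraint-based calling worth knowing: the longest
feasible window around a truly autozygous segment extends through flanking
SNPs that are homozygous by chance, plus the allowed heterozygous/missing
budget. Boundary over-extension by a few inter-SNP intervals is therefore
inherent to the semantics (any caller honouring the stated constraints
does it); truth-set recovery is accordingly scored as coverage of the true
segment — the suite requires at most one uncovered inter-SNP interval at
each boundary, no interior holes, and at most 1% of calls without truth
support.

F_ROH divides the summed run length by the array-covered autosomal genome
length, 944,270 kb for the standard chicken 600K map (chromosomes 1–28).
For any other map the denominator is the summed per-chromosome marker
span, reported via a message — this keeps simulated genomes comparable to
their own map rather than to the chicken constant. Runs are also binned
into the seven conventional length classes (1–5], (5–10], … (25–30],
>30 Mb (right-closed), and summarised per breed as the mean per-animal Mb
in each class.

## Incidence track and islands

For each mapped SNP the incidence is the number of animals with a run
covering it (closed interval; one animal counts once) divided by the total
number of animals. Island detection selects SNPs at or above the empirical
`1 − topFraction` quantile of the whole track — zero-incidence SNPs
included, since the threshold is meant to be a genome-wide tail — and
merges selected SNPs on a chromosome while consecutive selected SNPs are
at most `mergeGapKb` apart. Defaults: `topFraction = 0.001` (the "top
0.999%" convention read as the upper 0.1% tail; the phrase is ambiguous,
so the parameter is mandatory-logged) and `mergeGapKb = 1000`, mirroring
the ROH gap rule because no independent merge rule is established. Island
coordinates are member-SNP positions; a degenerate track (all proportions
equal) errors unless forced. Annotation is a plain closed-interval overlap
against user-supplied BED/GFF features; touching endpoints count.

## Population structure

* **IBS distance** between individuals: 1 minus the mean per-marker
  allele-sharing similarity (2 − |g_a − g_b|)/2 over markers typed in
  both (pairwise deletion).
* **Classical MDS / PCoA** via double-centering and eigendecomposition
  (`stats::cmdscale`); axes with non-positive eigenvalues are dropped,
  reducing k with a warning. Breed-level pictures default to embedding
  individuals and averaging coordinates per breed, with averaging of the
  distance matrix first as an option.
* **Reynolds distance** between breeds, from within-breed frequencies:
  θ = Σ_l 2(p_x−p_y)² / Σ_l 2(1 − p_x p_y − q_x q_y), loci undefined in
  either breed skipped, with an optional −ln(1−θ) linearization. The
  large-sample estimator is used; the fully bias-corrected
  sample-size-weighted variant is out of scope and would shift distances
  only for very small cohorts.
* **Neighbor joining** on either matrix (via `ape`), negative branch
  estimates clamped to zero with a warning; NJ is exact on additive
  matrices, which the test suite uses as its oracle. Newick serialization
  quotes labels containing metacharacters (single quotes, doubled
  internally), since several breed labels contain parentheses or hyphens.

## Synthetic data and what it does (not) validate

The generator builds: a uniform random marker map; ancestral frequencies
p0 ~ Beta(1.5, 1.5) (a mildly flattened array-like spectrum); per-breed
frequencies from the Beta drift model p ~ Beta(p0(1−c)/c, q0(1−c)/c),
whose divergence parameter c satisfies E[(p_x−p_y)²] = 2c·E[p0 q0] for
independent breeds; HWE genotypes with optional sitewise inbreeding
(p² + Fpq / 2pq(1−F) / q² + Fpq) and i.i.d. missingness; and injected
autozygous segments that set every marker in a span to a homozygous code
drawn by its allele frequency (clearing heterozygous and missing calls
inside the span, so injected truth is exactly recoverable).

The bundled 27-breed study fixture emulates a national survey of local
chicken breeds: 23 local breeds of 20–24 animals with stronger drift
(c = 0.15) and 4 commercial stocks of 9–13 animals (c = 0.05), 582 animals
in total, on 5 autosomes × 40 Mb with 1600 SNPs each (8,000 markers;
problem size chosen so the full pipeline runs in about a minute), 0.5%
missingness, per-breed target autozygous fractions spanning 0.03–0.607
realised purely by segment injection (1–30 Mb, placed to a coverage
target; sitewise inbreeding 0 so that F_HOM and F_ROH estimate the same
quantity), and one designed island region injected in 90% of all animals.
Sample sizes and the target fractions follow the published survey design
so that recovered magnitudes are comparable to the published ones.

Because genotypes are sitewise independent outside injected segments, the
fixture validates the caller's contracts (constraints, selection,
coordinates, truth recovery) and the estimators' calibration — it does not
emulate linkage disequilibrium, genuine IBD mosaics, genotyping error
or array ascertainment. Passing tests therefore certify the algorithms and
conventions, not the biology of any particular real dataset.

## Numerical and degenerate-input choices

* Quantiles use R's default type-7 interpolation; with heavy ties (the
  designed-hotspot fixtures) the threshold lands exactly on the tied
  value, making selection reproducible.
* `F_i` is undefined (NA, warned) when L_i = E_i; markers fixed in the
  cohort contribute identically to O and E and thus cancel.
* Distance pairs sharing no typed marker error by default
  (`allowMissingPairs = TRUE` returns NA).
* All-zero distance matrices embed to a single zero axis; NJ refuses
  non-symmetric input; empty ROH sets yield empty but well-formed tables.
* All generators are deterministic under a single integer seed; the
  pipeline writes outputs atomically and its manifest contains no
  timestamps, so identical runs are byte-identical.

## Known limitations

* Window mode reproduces the heuristic's shape but is not bit-compatible
  with any specific external tool build; segment mode is the reference
  semantics.
* The Reynolds estimator omits the small-sample correction (see above).
* Binary PLINK (BED/BIM/FAM) and VCF ingestion, Hardy–Weinberg and
  relatedness filtering, model-based ancestry estimation and
  neighbor-net graphs are out of scope.
* Island annotation is generic interval overlap; no database lookups are
  performed.
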