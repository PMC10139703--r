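---
title: "Methods: linking differential methylation to pooled-sequencing diversity"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: linking differential methylation to pooled-sequencing diversity}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methdiv)
```

This vignette is the package's own account of its models and the design
choices behind them. The pipeline couples two data types from the same pair
of diverging populations: per-CpG bisulfite read counts from a few
individuals per population (with treatment samples from a salinity-transfer
style experiment), and whole-genome pool sequencing of each population. The
question it serves is whether sites whose methylation state diverges, varies
or responds to the environment also carry elevated standing genetic
variation.

## Site filtering

A CpG site enters the analysis only if it is covered at least `min_cov`
(default 5) times in *every* sample; sites on excluded chromosomes
(mitochondrial and the two sex chromosomes by default) and sites in a
user-supplied SNP mask are removed, and sites that are uniformly 0% or
uniformly 100% methylated across the main-comparison samples are dropped as
uninformative. Sites absent from a sample are treated as zero coverage
there, never imputed. The file's percent-methylation column is ignored and
recomputed from the counts, which avoids mixing two rounding conventions.
Coordinates are 1-based throughout; BED inputs (0-based, half-open) are
converted on read, so a BED interval `[100, 200)` covers 1-based positions
101–200 and a point p lies inside iff start < p ≤ end. Positions are taken
as given and never strand-merged: the consumed coverage files are assumed
to be strand-combined upstream, and duplicate records within a sample are
an error rather than silently merged.

## The differential methylation test

Per site, methylated/unmethylated counts are modelled by binomial logistic
regression on group membership and tested with the likelihood-ratio
chi-square (1 df). Because the only covariate is a two-level factor, the
group MLEs are the coverage-pooled per-group proportions and the statistic
reduces to the G-test on the pooled 2×2 table; the implementation is that
closed form, vectorised over sites, and the test suite verifies it equals
`glm(..., family = binomial)` deviance differences to 1e-8. Fisher's exact
test on the pooled counts is the fallback for non-finite statistics and the
independent oracle in tests (rank agreement ρ > 0.99 on simulated panels).

The methylation difference defaults to the difference of coverage-weighted
pooled percentages (B − A); an unweighted mean-of-samples convention is
available (`diff_method = "mean"`). With equal coverages the two coincide;
they differ when coverage is unbalanced within a group, and the pooled form
matches the counts actually tested.

Multiple testing uses Benjamini–Hochberg over all sites of a comparison.
The q-values are computed per comparison (population, marine treatment,
freshwater treatment) rather than jointly, since each comparison is its own
family. Classification is inclusive at both boundaries: `hypo` iff
Δmeth ≤ −15 and q ≤ 0.05, `hyper` iff Δmeth ≥ +15 and q ≤ 0.05. The same
rule defines inducibility in the treatment comparisons; the direction of an
induced change is deliberately ignored and only its magnitude |Δmeth| is
carried forward. Overdispersion correction is not applied: with 2–3
individuals per group a dispersion estimate is itself so noisy that it
mostly adds variance, and the inclusive effect-size threshold already
guards against coverage-driven significance.

## Pool-seq estimators

Pileup decoding counts `.`/`,` as the reference base, letters as stated,
consumes `^` (with its mapping-quality byte), `$` and indel runs without
counting, drops `*`/`N`, and drops bases under the quality threshold
(phred+33, default 20). A vectorised fast path handles columns without
special characters; a scalar scanner handles the rest, and a decoded
base/quality length mismatch is an error pointing at the offending line.

With post-filter counts c_a at coverage M (alleles with fewer than
`min_count` = 2 reads zeroed as probable sequencing error; sites kept when
3 ≤ M ≤ 1000):

* naive π = (M/(M−1)) (1 − Σ (c_a/M)²) — algebraically the number of
  pairwise read differences divided by C(M,2), which the tests verify by
  exhaustive enumeration of every configuration up to 8× coverage;
* S = 1 iff ≥ 2 alleles survive the min-count filter; naive θ = S/a₁(M)
  with a₁ the harmonic number.

The naive statistics are biased for pool diversity: reads resample the same
haploids, and the min-count filter silently converts weakly covered
polymorphisms into monomorphic sites. In the default `pool_corrected` mode
each statistic is divided by its expected value for a site segregating in a
pool of n haploids, computed by exact enumeration: pool minor-allele counts
k = 1..n−1 weighted by the neutral 1/k spectrum, read counts binomial at
coverage M, the min-count filter applied. For π the correction is

C_π(M, n, b) = Σₖ (1/k) Σ_{r=b}^{M−b} Binom(r; M, k/n) · (M/(M−1)) · 2(r/M)(1−r/M),

normalised so that the weighted true heterozygosity is 1; with no filter it
collapses to the classical pool factor (n−1)/n. For θ the analogous
quantity is the weighted detection probability, and the corrected statistic
is S/(a₁(n) · E[P_detect]). The corrections are cached per (M, n, b) and
validated against a Monte-Carlo oracle: across pools of 20 and 24 haploids,
depths 5 and 10 and min-counts 1 and 2, the mean corrected π over 10⁵
simulated sites sits within three standard errors of the true mean
heterozygosity while the naive estimator shows the predicted downward bias.
One boundary is worth knowing: at coverage below twice the min-count
(M < 2b, e.g. M = 3 with b = 2) a site can never be observed as segregating,
so it contributes zero to the label mean while still counting as covered;
at the default depths this affects a small fraction of sites and is shared
by any estimator under these filters.

Label-level estimates are per-site averages over covered sites, with the
covered fraction (covered/labelled) reported and labels under a 60% floor
flagged, mirroring the exclusion rule used for ranks. Tajima's D uses the
classical constants (verified against exact rational arithmetic for
n = 2..10) on the *naive* per-site sums, at an effective sample size
n_eff = min(pool haploids, median covered-site coverage). The pooled
adaptation of D's variance used by the original pool-seq toolkits is not
fully specified in the literature this package works from; this n_eff
convention is a declared reconstruction, configurable in spirit by passing
`tajimas_d()` any n_eff, and D values should be read as comparative across
labels rather than as calibrated test statistics.

## Fst

Per site, within-pool heterozygosities use the M/(M−1) small-sample factor
and the total heterozygosity is computed from the mean allele frequencies
with the combined-coverage factor (M₁+M₂)/(M₁+M₂−1); Fst is
(h_T − h̄)/h_T, defined only where h_T > 0 (i.e. at sites polymorphic in
the merged frequencies — Fst is a property of variable sites). The
min-count filter is applied to counts summed across pools by default, with
a per-pool option. Under this convention identical finite pools give a
slightly *negative* value (−1/18 at 10×+10×), vanishing as coverage grows;
per-site values are therefore retained unclamped so label means stay
unbiased, with `clamp = TRUE` available for display. The convention is
pinned by a hand-derived fixture (pools {C:10} and {C:5,T:5} give exactly
8/27) frozen in the tests.

## Matched subsampling and ranks

Non-DMCs are matched to DMCs by drawing, for each DMC in sorted order, one
uniform non-DMC within ±2 kb on the same chromosome, then deduplicating.
Sampling is with replacement across DMCs before deduplication, a single
seed drives the whole draw, and uniformity among candidates is verified by
a chi-square test over 10⁴ seeds. The 2 kb default follows the procedural
description of the source analysis (its figure legend says 2 Mb; the more
specific methods wording was adopted and the window is a parameter).

Ranks are equal-width bins over [min, max] of the ranking variable
(mean PM, SD of methylation, their differences, or absolute induced
change): left-closed right-open except the last interval, values exactly on
an internal boundary go up, undefined values are skipped and counted.
Equal-width (not equal-frequency) matches the binning utility convention of
the source analysis; ranking is done separately per population and per site
category, over each population's own value range. Rank-level diversity
reuses the label aggregation with rank labels, and ranks under the 60%
covered-fraction floor are excluded before trend fitting.

## Paired statistics

Per-chromosome values are compared pairwise: Shapiro–Wilk on the
differences gates between a paired t-test (normal-looking, p > 0.05) and a
paired Wilcoxon signed-rank test (exact for n ≤ 25, normal approximation
with continuity correction above, zeros dropped). All-zero differences are
reported as a degenerate comparison with p = 1 rather than an error. Trend
fits are ordinary least squares with the slope's two-sided p and adjusted
R² = 1 − (1−R²)(n−1)/(n−2); the adjusted value is reported because it can
go negative for null fits, which makes "no trend" visible rather than
rounding it to zero. No correction is applied across the battery of paired
comparisons — they are reported as raw paired-test p-values, matching the
reporting convention of the analyses this package reimplements.

## The synthetic generator

The generator exists so every stage — and their composition — can be tested
against exact truth. Its defaults are the study conditions the pipeline
assumes: 11 RRBS samples (3 marine native, 3 freshwater native, 3 marine
transplanted, 2 freshwater transplanted — the unbalanced n = 2 group is
kept on purpose), pool sizes 24 and 20 haploids, mean pool depths 10.4×
and 8×, mean RRBS depth 20× floored at 5×. Methylation means are drawn per
class: a bimodal beta mixture at non-DMCs (modes near 0 and 1, 55% weight
on the methylated mode), high-to-intermediate shifts at hypo sites and
low-to-high shifts at hyper sites, with the between-population contrast
kept at ≥ 25 percentage points so that detection power, not effect
existence, is what the recovery tests measure. Between-individual
variability is beta noise whose precision differs by class and population
(freshwater-hypo loosest, mirroring the variance structure the analysis is
designed to detect). Induced fractions per class default to 3.8%, 11.3%
and 39.2% of sites induced in either population, converted to a
per-population rate; induced shifts are ≥ 25 points toward the opposite
extreme. Polymorphism probabilities are ordered hyper > hypo > non-DMC
(0.16/0.10/0.05 in marine) and scaled by a bottleneck factor 0.7 in
freshwater; alternate-allele frequencies are beta-distributed; SNP types
are C-T/G-A with probability 0.90 (marine-led sites) or 0.94
(freshwater-only sites). A configurable fraction of sites (2%) carries a
simulated C-T SNP among the RRBS individuals and goes into the emitted SNP
mask. Desk-scale default class counts are 5000/4500/750 over six
chromosomes with ~500 bp spacing, which keeps 2 kb matching windows
populated; the test suite runs the defaults and the acceptance script runs
a 100,000-site configuration (50k/40k/10k).

What the generator deliberately does *not* emulate: genealogies (allele
frequencies are drawn, not evolved — the analysis consumes frequencies, so
coalescent machinery would add cost without adding truth); linkage between
sites; sequencing error beyond the quality threshold; strand structure or
read-level artefacts; any built-in correlation between inducibility and
polymorphism (so the pipeline's inducibility–diversity trend fit is
expected to be null on default synthetic data, and the rank-trend recovery
test instead constructs sites whose heterozygosity tracks the ranking
variable by design). Real-data folded site-frequency spectra are also not
matched — the beta frequency model yields more intermediate-frequency
variants than a neutral spectrum, which is why synthetic Tajima's D values
come out positive; the estimators' calibration is established separately
under the neutral spectrum by the Monte-Carlo checks. Passing recovery
tests therefore demonstrate that the pipeline's inference machinery is
correct and well-calibrated under its stated model, not that any particular
biological result is guaranteed on real data.

A single master seed drives everything through named substreams (one per
emitter), so regenerating one output never perturbs another and reruns are
byte-identical.

## Numerical and edge-case conventions

* p-value of the LRT at a boundary MLE uses 0·log 0 = 0; the statistic is
  floored at 0 against rounding.
* Ranks with all values identical are a configuration error (degenerate
  range), as is classifying an empty DM stream or a group with no samples.
* A single-sample group reports SD of methylation as absent (NA), not 0.
* Sites covered in only one pool are skipped by Fst; labels with no defined
  per-site Fst are reported absent.
* Tajima's D is absent when no site segregates; S_total < 0 is an error.
* The DM caller's null calibration model used in tests draws per-site
  methylation from Unif(0.2, 0.8) at coverage max(5, Poisson(20)) per
  sample — bounded away from the 0/1 boundaries so the chi-square
  approximation is what is being tested, not boundary degeneracies.
* Operating points frozen after a one-off calibration run of the default
  generator: DM sensitivity ≥ 0.80 with false discovery proportion ≤ 0.10,
  induced-site sensitivity ≥ 0.70 including the n = 2 treated group. These
  are regression floors, not claims about real data.

## Limitations

The package consumes upstream outputs (alignment, methylation calling,
bisulfite-aware SNP calling) and inherits their quality; the SNP mask in
particular bounds how well C-T artefacts are excluded. The biallelic SNP
detector is a count-threshold rule, not a genotype-likelihood caller, a
deliberate substitution that keeps the dependency surface small and the
behaviour transparent. Region-level (DMR) analysis, covariate adjustment,
beta-binomial shrinkage and sliding-window Fisher tests are out of scope.
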