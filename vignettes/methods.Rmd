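---
title: "Methods: selection, copy number and gene conversion at duplicated loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: selection, copy number and gene conversion at duplicated loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(sdpopgen)
```

This vignette documents the statistical methods, the model assumptions
behind the synthetic data, and the numerical choices made where the
methods leave room for judgement.

## 1. The coalescent simulator

`simulate_coalescent()` implements a structured coalescent backwards in
time. Its assumptions:

- **Single non-recombining genealogy per window.** Each simulated window
  is one tree. A recombination rate can be recorded in the model but is
  not simulated; analyses that need independence across windows obtain it
  by simulating windows independently (the windowed statistics and null
  distributions do exactly that). This is the main simplification
  relative to real sequence data, where linkage decays continuously.
- **Coalescence and migration as competing exponentials.** With k
  lineages in a population of (time-varying) diploid size N(t), the pair
  coalescence rate is k(k−1)/(4N(t)) per generation. Piecewise
  exponential growth is handled in closed form by inverting the
  integrated hazard, so no time discretization is involved. Backwards
  migration is a constant per-lineage hazard between rate changes.
- **Events.** Population splits (all lineages of the derived population
  move to the ancestral one, backwards in time), size/growth changes,
  and migration-rate changes, all at fixed times in generations.
- **Ancient sampling.** Samples may enter the genealogy at t > 0,
  emulating dated archaic genomes; tips then sit above the present by
  their sampling age.
- **Infinite sites.** Mutations are Poisson on branches with rate μ per
  bp per generation, placed at unique integer positions (rejection
  sampling); every variant is biallelic with known ancestral state.
  There is no back-mutation and no mutation-rate heterogeneity.

Times are generations throughout; years appear only in reporting, via a
generation time stored in the model (default 29).

## 2. Selection statistics and null inference

The site frequency spectrum is computed from complete-case haplotypes
per window (haplotypes with any missing call in the window are dropped
for that window only). Sites fixed derived in the sample are excluded
from the segregating-site count but retained for Thomson's estimator,
which needs the total derived-mutation count per haplotype.

- Tajima's D uses the 1989 normalization constants; windows with S = 0
  return `NA` rather than 0 (an invariant window carries no evidence).
  Samples of fewer than 4 haplotypes are refused.
- Fay & Wu's H is reported unnormalized by default, H = θ_π − θ_H with
  θ_H = Σ 2 i² S_i / (n(n−1)); the normalized variant is available.
- Thomson's TMRCA is (1/n) Σ d_i / (μL) with d_i the derived-mutation
  count on haplotype i.
- LD is computed per pair as D, Lewontin's D′ = D/D_max, and r².

Empirical p-values are add-one throughout: p = (r + 1)/(n + 1), so no
test ever reports zero. The window-set selection test aggregates a
region's windows by their **median** statistic and compares it against
medians of equally sized window sets resampled from the null. The null
can come from a coalescent simulation (`simulate_null_distribution()`)
or from a genome-background table (`read_background_null()`); a null
with fewer than 100 values is an error and fewer than 1,000 a warning,
since add-one p-values saturate at 1/(n+1).

A deliberate calibration note: over continuous statistics the window-set
p-value is uniform under the null (the acceptance tests verify this with
a Kolmogorov–Smirnov check). The copy-number permutation test below is
conservative rather than uniform, because permuted V_ST values tie over
integer copy numbers; its acceptance criterion is therefore one-sided
type-I validity.

## 3. Copy-number differentiation

V_ST = (V_T − V_S)/V_T compares total variance with the
sample-size-weighted mean of within-population variances (population
variances, i.e. divide-by-n, so weights are exact). A locus with no
variance at all is defined as V_ST = 0. Significance is by label
permutation with add-one p-values. The latitude regression fits
`|CN| ~ latitude + PC1..PCk` by least squares and names the offending
covariate when the design is rank-deficient. Donor/acceptor correlation
is a plain Pearson test; reciprocal gene conversion predicts negative R.

## 4. Interlocus gene conversion

Identity profiles slide a 500-column window at a 100-column step over a
pairwise alignment. Gap columns count as mismatches by default
(`gap-mismatch`) — conservative, since an insertion interrupts identity —
with `gap-exclude` available. An empirical conversion tract is a maximal
run of **more than two** consecutive windows at exactly 100% identity;
the comparison is to literal 1.0 with no epsilon, because a single
mismatch in a 500 bp window (499/500 = 0.998) must not count as perfect.
Tract spans are reported from the first window's start to the last
window's end and can be projected from alignment columns to ungapped
sequence coordinates.

The synthetic generator (`plant_igc()`) produces a paralog pair at a
chosen background divergence with mismatches placed independently per
site and a tract where the donor is copied over the acceptor. It makes
no attempt to model indels, mutation clustering, or partial/ancient
conversion tracts — detection performance on it bounds the idealized,
not the practical, case.

Full-length transcript-read assignment (`assign_flnc_reads()`) applies
the thresholds appropriate for near-identical paralogs: identity
strictly above 0.99, alignment overlap ≥ 200 bp, ORF ≥ 200 aa,
multimapping placements kept within 0.01 percentage points of the
read's best placement, and isoforms supported by strictly more than 10
reads.

## 5. Haplotype clustering

Haplotype PCA centers the binary matrix by column and takes scores from
the SVD; the number of informative components is the smallest N whose
components jointly explain more than 90% of the variance. k-means uses
k-means++ seeding (`stats::kmeans` has none) with 10 restarts. The
elbow rule chooses the smallest k whose WSS drop to k + 1 falls below a
threshold δ; δ defaults to 0.5% of WSS(1) so it scales with the data
(the fixed value of 500 used at the original locus is data-scale
specific). To keep the WSS trace monotone — a requirement for the elbow
reading to be well-defined — clustering at k + 1 additionally tries an
initialization built from the best k-solution's centers plus the
worst-fit point.

Haplotype heterozygosity is (n/(n−1))(1 − Σ p_c²) over cluster
frequencies. The homogeneity test asks how often m haplotypes drawn from
the modern pool (without replacement by default) fall into a single
cluster; with replacement the closed form is Σ p_c^m.

## 6. Synthetic data: what it does and does not emulate

The generators cover the statistical structure the methods consume:
frequency spectra with realistic coalescent variance, ancient samples at
depth, population-structured integer copy numbers as sums of two haploid
cassette-count draws, and paralog pairs with exact planted conversion
tracts. They do **not** emulate read-level artefacts (mismapping,
coverage noise in CN estimation), recombination within a window,
gene-conversion homogenization of the frequency spectrum, or
reference-bias effects — conclusions about robustness to those must come
from real data.

Problem sizes used in the examples and tests are this package's own
choices, selected so the full suite runs in minutes: 2 kb windows with
θ = 10 per window, samples of 10–40 haplotypes, null distributions of
1,000–2,000 windows, 30 kb paralog alignments at 2% divergence, and
copy-number panels of 50–200 samples.

## 7. Decisions on under-specified points

- The elbow criterion is read as "stop when the WSS *drop* falls below
  δ", i.e. WSS(k) − WSS(k+1) < δ; the literal difference in the other
  direction is trivially negative and never selects.
- Windows at the end of a region shorter than half a window are merged
  into the previous window; at least half a window stands alone.
- `tajima_d` returns `NA` (not 0) for invariant windows, and windowed
  aggregation simply drops `NA` windows with a message.
- Boundary conventions are strict and tested: QUAL < 20 removed (20
  kept), SNVs within ≤ 10 bp of an indel removed, samples with > 10%
  missingness removed (exactly 10% kept), MAF filter keeps sites
  strictly above the threshold, identity must be strictly above 0.99,
  isoforms need strictly more than 10 reads.
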