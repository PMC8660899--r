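---
title: "Stage-paired differential analysis of oocyte and embryo proteomes"
author: "ovoproteome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Stage-paired differential analysis of oocyte and embryo proteomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ovoproteome)
```

## The problem

Hormonal superovulation is the standard way to obtain many mouse
oocytes at once, but the oocytes it yields may differ from naturally
ovulated ones. The design this package analyzes profiles both
treatments along the preimplantation series — oocyte, 1-cell, 2-cell,
4-cell, 8-cell, morula, blastocyst — with replicate pools per stage and
treatment, in two modalities: a label-free proteome (iBAQ intensities)
and a companion transcriptome (counts). The scientific questions are
(i) which proteins respond to the treatment consistently across the
series, (ii) whether the treatment signal is visible in the sample
structure (clustering, PCA), and (iii) whether the transcriptome shows
the same contrast (it largely does not, which makes it a natural
negative control for the pipeline).

## Normalization model

Protein intensities are made comparable within a sample by the riBAQ
transform, `riBAQ_i = iBAQ_i / sum_i iBAQ_i`, a molar-fraction-like
quantity: each sample's detected values sum to one. Detection is
defined on the linear scale as value > 0; blank and zero cells are
equivalent and stay undetected through every step (no imputation,
ever).

The feature filters are:

* **minimum detection** — a feature must be detected in at least 2 of
  the samples (inclusive boundary), otherwise it is discarded;
* **constitutive expression** — for the paired test a feature must be
  detected in at least one replicate in *every* stage x treatment cell
  (14 cells in the full design). This is the set on which pairing is
  complete by construction.

Replicates are then averaged (mean of the detected values; the single
value when only one replicate detected the protein), the averaged
columns are quantile-normalized, and values are log10 transformed.
This order — average, then quantile, then log — follows the processing
narrative of the study the package reimplements; the alternative
(quantile before averaging) is available by composing the exported
steps by hand. Quantile normalization delegates to
`limma::normalizeQuantiles(ties = TRUE)`: every column is mapped onto
the mean of the order statistics, ties receive the mean of their
reference values, and `NA` (undetected) cells are simply excluded from
the rank pool — the pool-restriction policy for partially detected
features. After the constitutive filter and averaging the matrix is in
practice fully detected, so the policy matters only when the test is
run at replicate resolution.

The transcript track does not attempt a regularized-log transform.
It uses median-of-ratios size factors (each sample's factor is the
median, over features with all-positive counts, of the count over the
feature's geometric mean — anchored so a doubled library gets factor
sqrt(2) against 1/sqrt(2)) followed by `log2(count / sf + 1)`. This is
a deliberate, documented stand-in: it removes library-size differences
but applies no variance shrinkage. Since the transcript track's role
here is the null contrast, shrinkage subtleties are immaterial to the
conclusions the pipeline draws from it.

## The exact stage-paired test

For each feature the treatment contrast is a vector of paired
differences, one per stage:
`d_s = x_superovulation,s − x_natural,s` on the log10 scale. The test
statistic is the Wilcoxon signed-rank statistic
`T = sum sign(d_s) * rank(|d_s|)` with mid-ranks for ties; zero
differences are dropped before ranking (the classical zero-exclusion
convention; Pratt's zero-rank variant is available via
`zero_policy = "pratt"`). Significance is assessed *exactly*: all `2^n`
assignments of signs to the fixed ranks are enumerated —
implementation-wise by a subset-sum convolution over doubled ranks,
cached per rank multiset, so thousands of tie-free features share one
distribution — and

    p = #{ |T*| >= |T_obs| } / 2^n .

Two-sidedness via `|T|` of the sign-flip distribution is well defined
under ties (where doubling a one-sided tail is not). The p-value floor
is `2 / 2^n`. BH correction is applied once across all tested features
of a modality, never per stage.

**The pairing-mode question.** With the seven stage pairs the floor is
`2/2^7 = 0.015625`. A BH step-up at FDR < 0.1 over ~2800 features then
needs at least `ceiling(0.015625 * 2844 / 0.1) = 445` features *at the
floor* before a single discovery is possible — so a few-hundred-
discovery outcome, as reported for designs of this shape, is
arithmetically unreachable in pure stage pairing. The package therefore
implements two modes:

* `pairing = "stage"` — the literal seven-pair design; useful for the
  fold-change census and structure work, essentially powerless for BH
  discovery at this scale;
* `pairing = "stage_replicate"` — one difference per stage x replicate
  (up to 14 pairs, floor ≈ 1.22e-4), which restores power and controls
  the realized FDR in simulation.

Both modes are first-class and tested; the discrepancy is documented
rather than resolved, because the upstream description does not pin
down the effective replicate handling.

Features with fewer than two complete pairs are reported with `p = 1`
and an `insufficient_pairs` flag — never dropped silently.

## Fold changes, census and direction calls

Per-stage fold changes are computed on the *linear* replicate-averaged
riBAQ scale as superovulation/natural; a stage where one treatment is
undetected contributes no fold change (no infinities). The census
counts features with `max(FC, 1/FC) >= t` per stage for thresholds
4, 5, 6, 7, 8 (inclusive boundary). The up/down classification among
significant features requires the maximal stage fold change to *strictly
exceed* the cutoff ("in excess of twofold") and takes the direction
from the sign of the median stage log fold change.

## Structure diagnostics

Clustering and PCA operate on the replicate-averaged expression values
(one column per stage x treatment — those are the units the study
design displays). Sample distance is `1 − r` with Pearson `r` (the
plain transform, not `(1−r)/2` or `1−|r|`); clustering is complete
linkage via `stats::hclust`; trees serialize to Newick with branch
lengths equal to parent-minus-child merge heights. PCA is centered and
unscaled via `stats::prcomp` on log expression values. A component
"separates" the treatments when a scalar threshold puts all
superovulation scores strictly on one side; because perfect separation
is brittle at 14 samples, the point-biserial correlation is reported
alongside. Heatmap row order comes from a complete-linkage tree on
Euclidean feature distances, with a canonical subtree orientation
(smallest label first) so the order is independent of input row order.

## Enrichment

Over-representation is the exact hypergeometric upper tail
`P(X >= k)` of the query/term overlap within a chosen universe. The
universe defaults to the analyzed (constitutive) feature set rather
than a whole genome — detection bias makes genome universes
anti-conservative here. Term-level BH is applied across the collection
(enriched at q <= 0.01 by default). The ranking score is Enrichr-style:
a Monte-Carlo z of the deviation of the term's p-value rank from its
rank under random queries of the same size (seeded, 1000 resamples by
default), combined as `-ln(p) * z` so that enriched terms — small p,
better-than-expected rank — get positive scores. The z convention
reported is `(mean_rank − observed_rank)/sd`, positive when the term
ranks better than chance; the combined score applies the sign flip so
its own sign is interpretable. Identifiers are matched
case-insensitively after whitespace stripping, and query ids missing
from the universe are an error, not a silent drop.

## Phenotype statistics

Morphometry: the ooplasm diameter is the traced perimeter divided by
pi; the volume is the spherical approximation `(4/3)π(d/2)^3` at
1 pL = 1000 µm³ (diameters of 79.4 and 78.1 µm give 262 and 250 pL).
Count-table comparisons use Fisher's exact test (two-sided by
probability-mass summation, the convention that reproduces p = 0.202
on the embryo-transfer table `[[6,7],[2,10]]`), the chi-square test of
homogeneity without continuity correction (flag available), and the
two-sample Wilcoxon rank-sum test — exact by enumeration for small
untied samples, tie-corrected normal approximation otherwise, with the
mode recorded in the result.

## The synthetic-data generator

`sim_config()` freezes the study conditions the package is validated
under: 7 stages x 2 treatments x 2 replicate pools, 2000 protein
features, baseline log10 riBAQ ~ Normal(−5, 1). Its structural choices
mirror the qualitative findings the real design exhibits:

* a *shared developmental trajectory* (`stage_curve`), nearly flat
  from oocyte to 8-cell and jumping at morula/blastocyst, scaled per
  feature by a Normal(0, 1) coefficient. This makes the morula +
  blastocyst samples form their own supercluster while pre-morula
  samples, whose stage differences are small, cluster by treatment —
  and it concentrates the developmental signal in one principal
  component so the treatment contrast surfaces as PC2;
* a treatment effect on `pi_de = 10%` of features, log10 magnitude
  `delta = 0.6`, with stage profile `(0.5, 0.6, 0.75, 0.9, 1.0, 0.7,
  0.4)` peaking at the 8-cell stage and smallest at the blastocyst —
  the fold-change census consequently peaks at 8-cell. The census
  minimum sits at the blastocyst for the validation seed; under
  reseeding it can swap with the other low-effect boundary stages,
  whose expected counts are within a few features of each other;
* affected features biased toward high abundance
  (`de_abundance_weight = 1`), so the differentially expressed set is
  systematically more abundant than the parent proteome
  (`abundance_shift_check()` verifies this);
* replicate noise sd 0.2 (log10) and logistic abundance-dependent
  dropout `P(detect) = plogis(10 + 1.2 * log10(value))` (~97% of cells
  detected; the low-abundance tail exercises the detection and
  constitutive filters without starving the paired test);
* a transcript track of 20 000 negative-binomial features (dispersion
  0.05, log-normal library factors) sharing the trajectory shape with
  treatment effect `delta_t = 0` — the null contrast: the pipeline
  finds no significant transcripts, and no principal component
  separates the treatments.

What the generator does *not* emulate: correlated protein modules,
batch/run effects, peptide-level error propagation, SILAC/TMT channel
artifacts, or missingness that is not abundance-driven. Passing tests
on this generator therefore demonstrate correctness of the statistical
machinery and recovery under the stated noise model, not robustness to
every artifact of real LC–MS/MS data.

Validation problem sizes were chosen to keep the full suite quick while
leaving the conclusions stable: 2000 protein features for recovery and
null-calibration runs, 20 000 transcript features for the null
contrast, 100-instance oracle sweeps for the exact test and Fisher
test. All generation is bitwise reproducible from `(config, seed)`, and
generator functions restore the caller's RNG state.

## Numerical choices and degenerate inputs

* Exact permutation enumeration is bounded at n = 20 nonzero pairs;
  beyond that the function errors and asks for an explicit choice
  rather than silently approximating.
* Mid-ranks are doubled to integers before the subset-sum convolution,
  so tail counts are exact integer arithmetic in doubles (no tolerance
  needed); `T_obs = 0` short-circuits to p = 1.
* An all-zero intensity sample, a constant sample vector in the
  correlation distance, a fully constant matrix in PCA, empty queries
  or universes in enrichment, and zero-margin contingency tables are
  all hard errors naming the offender.
* Newick serialization writes parent-minus-child branch lengths with
  `%.15g`; round trips through standard Newick readers preserve the
  ultrametric depths.
* Tables are written tab-delimited with 17-significant-digit values so
  write/read round trips are bit-identical.

## Known limitations

* The stage-pairing mode is faithful to the seven-pair description but
  has essentially no BH power at realistic feature counts (the floor
  arithmetic above); quantitative reproduction of discovery counts
  from the original deposited tables is contingent on the unresolved
  pairing convention and is not asserted by this package's tests.
* The shifted-log transcript transform is not a regularized log;
  low-count variance is not shrunk.
* The enrichment z-score is a Monte-Carlo construction; term-level
  scores depend on the resample seed (reported and fixed by default),
  and agreement with any particular web service's historical library
  versions is out of scope.
* Mixed-effect structure (litter effects, run batches) is not modelled
  anywhere.
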