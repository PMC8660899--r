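# ovoproteome

Differential-expression analysis for staged oocyte and preimplantation
embryo proteomes (and their companion transcriptomes) contrasting two
ovulation treatments — hormonally induced superovulation vs natural
ovulation — across the seven-stage developmental series oocyte, 1-cell,
2-cell, 4-cell, 8-cell, morula, blastocyst, each profiled in both
treatments with replicate pools.

It is written for quantitative proteomics / reproductive-biology
analysts who have label-free intensity tables (MaxQuant
proteinGroups-style iBAQ columns) or RNA-seq count matrices for such a
design and want the complete, testable analysis chain in R.

## What the package computes

**Normalization.** iBAQ intensities are converted to relative iBAQ
(riBAQ) molar fractions per sample,

    riBAQ_i = iBAQ_i / sum_i iBAQ_i ,

features detected (riBAQ > 0) in fewer than two samples are discarded,
the *constitutive* set (detected in at least one replicate in every
stage x treatment cell) is selected, replicates are averaged on the
linear scale, columns are quantile-normalized, and values are log10
transformed into "expression values". Transcript counts instead get
median-of-ratios size factors and a shifted log2 transform.

**The test.** For each feature, expression values are paired across
treatments — one difference per stage,

    d_s = x_superovulation,s - x_natural,s ,  s = 1..7 —

and tested with a two-sided *exact* sign-flip permutation test on the
Wilcoxon signed-rank statistic T = sum sign(d_s) rank(|d_s|): all 2^n
sign assignments are enumerated and p = #{|T*| >= |T_obs|} / 2^n.
P-values get Benjamini–Hochberg FDR control (q < 0.1). With n = 7 pairs
the attainable floor is 2/2^7 = 0.015625, which caps BH discoveries; a
stage-replicate pairing mode (up to 14 pairs, floor ≈ 1.22e-4) is
provided and is the mode with usable power at this design size (see the
methods vignette).

**Diagnostics and downstream.** Stage-wise fold-change census at
thresholds 4–8; complete-linkage clustering on Pearson correlation
distance with Newick export; PCA with a treatment-separation report per
component; hypergeometric gene-set over-representation with an
Enrichr-style combined score (-ln p times a Monte-Carlo rank-deviation
z); morphometry (diameter = perimeter/pi, sphere volume in pL) and
Fisher / Wilcoxon / chi-square phenotype tests. A synthetic-data
generator emulates the whole study design with ground truth, so every
stage of the pipeline is validated end to end without any downloads.

## Worked example

```r
library(ovoproteome)

gp <- generate_proteome(sim_config(), seed = 7)
gp$matrix
#> expr_matrix: 2000 protein feature(s) x 28 sample(s) [linear scale]
#>   detected cells: 96.6%
#>   stages: oocyte, 1-cell, 2-cell, 4-cell, 8-cell, morula, blastocyst

pp <- run_proteome_pipeline(gp$matrix, pairing = "stage_replicate")
summary(pp$de)
#> Stage-paired permutation DE (stage_replicate pairing)
#>   features tested:               1907
#>   significant (BH FDR < 0.1):     196
#>   of which > 2-fold:             up 101, down 92
#>   smallest attained p:           0.000122

rec <- evaluate_recovery(pp$de, gp$truth)
sprintf("sensitivity %.3f, realized FDR %.3f", rec$sensitivity, rec$realized_fdr)
#> "sensitivity 0.928, realized FDR 0.077"
```

1907 of the 2000 simulated proteins survive the detection and
constitutive filters; 196 are called at FDR < 0.1, of which 193 change
more than twofold somewhere in the series — and the truth comparison
shows 92.8% of the planted effects recovered at a realized FDR within
the nominal 0.1.

The structure diagnostics on the replicate-averaged expression values
(one column per stage x treatment):

```r
stage <- run_proteome_pipeline(gp$matrix, pairing = "stage")
treatment_separation(pca_samples(stage$expression))
#> treatment_separation: first separating component = PC2 (5.4% variance)
#>  component variance_fraction separates point_biserial_r
#>          1            0.7956     FALSE         -0.00621
#>          2            0.0537      TRUE          0.91914
#>          3            0.0174     FALSE          0.17830
#>  ...
```

PC1 carries the developmental trajectory; the treatment contrast
surfaces as the second component — the proteome-like behaviour. The
same call on a simulated transcriptome (null treatment effect) reports
no separating component.

Phenotype statistics work directly on printed study tables:

```r
fisher_exact_2x2(matrix(c(6, 7, 2, 10), 2, byrow = TRUE))$p_value
#> 0.2015561                      # pregnancy failures after embryo transfer
round(sphere_volume_pl(79.4))   # naturally ovulated oocyte, d = 79.4 um
#> 262
signif(sphere_volume_pl(78.1), 2)
#> 250
```

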