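#' End-to-end proteome analysis
#'
#' The full protein track: riBAQ normalization, minimum-detection
#' filter (>= `min_samples` samples), optional constitutive filter
#' (detected in at least one replicate in every (stage, treatment)
#' cell), replicate averaging on the linear scale, quantile
#' normalization, log10 transform, then the stage-paired exact
#' permutation test with BH FDR, plus the stage-wise fold-change
#' census. With `pairing = "stage_replicate"` the replicate columns are
#' kept for the test (up to 14 pairs) and only the fold-change matrix
#' is averaged.
#'
#' @param x linear-scale protein [expr_matrix()] of raw iBAQ
#'   intensities (or riBAQ fractions; renormalization is harmless).
#' @param pairing `"stage"` or `"stage_replicate"`.
#' @param fdr BH FDR threshold (default 0.1).
#' @param constitutive apply the constitutive filter (default `TRUE`).
#' @param min_samples minimum-detection filter (default 2).
#' @param fc_thresholds census thresholds (default `c(4, 5, 6, 7, 8)`).
#' @param zero_policy see [signed_rank_statistic()].
#' @return An object of class `ovo_pipeline`: list with `report`
#'   ([normalization_report()]), `expression` (normalized log10
#'   `expr_matrix` used for testing), `averaged` (linear
#'   replicate-averaged riBAQ), `de` (the [paired_de_test()] fit) and
#'   `census`.
#' @export
run_proteome_pipeline <- function(x,
                                  pairing = c("stage", "stage_replicate"),
                                  fdr = 0.1,
                                  constitutive = TRUE,
                                  min_samples = 2L,
                                  fc_thresholds = c(4, 5, 6, 7, 8),
                                  zero_policy = c("exclude", "pratt")) {
  pairing <- match.arg(pairing)
  zero_policy <- match.arg(zero_policy)
  rib <- compute_ribaq(x)
  md <- filter_min_detection(rib, min_samples)
  kept <- if (constitutive) filter_constitutive(md$matrix) else md$matrix
  report <- normalization_report(
    n_input_features = md$report$n_input_features,
    n_after_min_detection = md$report$n_after_min_detection,
    n_constitutive = if (constitutive) nrow(kept$values) else NA_integer_
  )
  avg <- average_replicates(kept)
  pre <- if (pairing == "stage") avg else kept
  expr <- log_transform(quantile_normalize(pre), base = 10)
  de <- paired_de_test(expr, pairing = pairing, alpha_fdr = fdr,
                       zero_policy = zero_policy, fc_matrix = avg)
  census <- fold_change_census(avg, thresholds = fc_thresholds)
  structure(
    list(report = report, expression = expr, averaged = avg,
         de = de, census = census, pairing = pairing, fdr = fdr),
    class = "ovo_pipeline"
  )
}

#' End-to-end transcriptome analysis
#'
#' The transcript track: minimum-detection filter on raw counts,
#' optional constitutive filter, median-of-ratios library-size
#' normalization with a shifted log2 transform (see
#' [normalize_counts()]), replicate averaging on the log scale, then
#' the same stage-paired exact permutation test. Fold changes come from
#' the size-factor-normalized linear counts.
#'
#' @inheritParams run_proteome_pipeline
#' @param x linear-scale transcript [expr_matrix()] of counts.
#' @return An `ovo_pipeline` object (see [run_proteome_pipeline()]).
#' @export
run_transcriptome_pipeline <- function(x,
                                       pairing = c("stage",
                                                   "stage_replicate"),
                                       fdr = 0.1,
                                       constitutive = TRUE,
                                       min_samples = 2L,
                                       fc_thresholds = c(4, 5, 6, 7, 8),
                                       zero_policy = c("exclude",
                                                       "pratt")) {
  pairing <- match.arg(pairing)
  zero_policy <- match.arg(zero_policy)
  md <- filter_min_detection(x, min_samples)
  kept <- if (constitutive) filter_constitutive(md$matrix) else md$matrix
  nc <- normalize_counts(kept)
  report <- normalization_report(
    n_input_features = md$report$n_input_features,
    n_after_min_detection = md$report$n_after_min_detection,
    n_constitutive = if (constitutive) nrow(kept$values) else NA_integer_,
    size_factors = nc$report$size_factors
  )
  lin <- expr_matrix(sweep(kept$values, 2L, nc$report$size_factors, "/"),
                     kept$design, scale = "linear",
                     modality = "transcript", detected = kept$detected)
  avg_lin <- average_replicates(lin)
  expr <- if (pairing == "stage") average_replicates(nc$matrix)
          else nc$matrix
  de <- paired_de_test(expr, pairing = pairing, alpha_fdr = fdr,
                       zero_policy = zero_policy, fc_matrix = avg_lin)
  census <- fold_change_census(avg_lin, thresholds = fc_thresholds)
  structure(
    list(report = report, expression = expr, averaged = avg_lin,
         de = de, census = census, pairing = pairing, fdr = fdr),
    class = "ovo_pipeline"
  )
}

#' @export
print.ovo_pipeline <- function(x, ...) {
  cat("ovo_pipeline (", x$de$results$feature_id |> length(),
      " features tested, ", x$pairing, " pairing)\n", sep = "")
  print(x$report)
  print(x$de)
  invisible(x)
}
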