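#' riBAQ: relative iBAQ normalization
#'
#' Converts per-sample iBAQ intensities to molar fractions: each
#' detected value is divided by the column sum over detected values, so
#' each sample's detected riBAQ values sum to 1. Undetected cells stay
#' undetected.
#'
#' @param x linear-scale protein [expr_matrix()].
#' @return A linear-scale `expr_matrix` of riBAQ fractions.
#' @export
compute_ribaq <- function(x) {
  if (x$scale != "linear") stop("compute_ribaq needs a linear-scale matrix")
  tot <- colSums(x$values)
  if (any(tot <= 0))
    stop("sample(s) with all-zero intensities: ",
         paste(colnames(x$values)[tot <= 0], collapse = ", "))
  v <- sweep(x$values, 2L, tot, "/")
  expr_matrix(v, x$design, scale = "linear", modality = x$modality,
              detected = x$detected)
}

#' Minimum-detection filter
#'
#' Discards features detected (value > 0) in fewer than `min_samples`
#' samples.
#'
#' @param x linear-scale [expr_matrix()].
#' @param min_samples minimum number of samples with detection (default
#'   2, i.e. features detected in fewer than two samples are discarded).
#' @return A list with `matrix` (the filtered `expr_matrix`) and
#'   `report` (a [normalization_report()]).
#' @export
filter_min_detection <- function(x, min_samples = 2L) {
  keep <- rowSums(x$detected) >= min_samples
  out <- subset_features(x, which(keep))
  rep <- normalization_report(n_input_features = nrow(x$values),
                              n_after_min_detection = sum(keep))
  list(matrix = out, report = rep)
}

#' Constitutive-expression filter
#'
#' Keeps exactly the features detected in at least one replicate in
#' every (stage, treatment) cell — with the full design, 7 stages x 2
#' treatments = 14 cells. This is the "constitutively expressed" set.
#'
#' @param x linear-scale [expr_matrix()].
#' @param stages stage vocabulary the design must cover (default the
#'   full seven-stage series).
#' @return The filtered `expr_matrix`.
#' @export
filter_constitutive <- function(x, stages = stage_levels()) {
  .check_full_design(x$design, stages)
  key <- .cell_key(x$design)
  cells <- unique(key)
  ok <- rep(TRUE, nrow(x$values))
  for (k in cells) {
    ok <- ok & rowSums(x$detected[, key == k, drop = FALSE]) >= 1L
  }
  subset_features(x, which(ok))
}

#' Average replicates within (stage, treatment) cells
#'
#' Collapses replicate columns to one column per (stage, treatment):
#' the mean of the detected replicate values, the single value when only
#' one replicate detected the feature, undetected when none did.
#' Scale-agnostic (the proteome pipeline averages linear riBAQ, the
#' transcriptome pipeline averages log2 expression).
#'
#' @param x an [expr_matrix()].
#' @return An `expr_matrix` with one column per (stage, treatment),
#'   sample ids `stage.treatment`, replicate 1.
#' @export
average_replicates <- function(x) {
  key <- .cell_key(x$design)
  cells <- unique(key)
  v <- matrix(NA_real_, nrow(x$values), length(cells))
  det <- matrix(FALSE, nrow(x$values), length(cells))
  vn <- values_na(x)
  for (i in seq_along(cells)) {
    sub <- vn[, key == cells[i], drop = FALSE]
    n_det <- rowSums(!is.na(sub))
    m <- rowMeans(sub, na.rm = TRUE)
    det[, i] <- n_det >= 1L
    v[, i] <- ifelse(det[, i], m, NA_real_)
  }
  parts <- strsplit(cells, "|", fixed = TRUE)
  d <- sample_design(
    sample_id = vapply(parts, function(p) paste(p, collapse = "."), ""),
    stage = vapply(parts, `[`, "", 1L),
    treatment = vapply(parts, `[`, "", 2L),
    replicate = rep(1L, length(cells))
  )
  if (x$scale == "linear") v[!det] <- 0
  dimnames(v) <- list(rownames(x$values), d$sample_id)
  expr_matrix(v, d, scale = x$scale, modality = x$modality,
              detected = det)
}

#' Quantile normalization
#'
#' Forces every sample column onto the common distribution given by the
#' across-column mean of order statistics (ties receive the mean of
#' their reference values). Undetected cells are excluded from the rank
#' pool and remain undetected; detected values of partially-detected
#' features are mapped through interpolated reference quantiles.
#' Delegates to `limma::normalizeQuantiles`.
#'
#' @param x an [expr_matrix()].
#' @return The quantile-normalized `expr_matrix` (same scale).
#' @export
quantile_normalize <- function(x) {
  v <- limma::normalizeQuantiles(values_na(x), ties = TRUE)
  if (x$scale == "linear") v[!x$detected] <- 0
  dimnames(v) <- dimnames(x$values)
  expr_matrix(v, x$design, scale = x$scale, modality = x$modality,
              detected = x$detected)
}

#' Log-transform an expression matrix
#'
#' @param x linear-scale [expr_matrix()]; all detected values must be
#'   positive.
#' @param base 10 or 2.
#' @return An `expr_matrix` on the `log10` or `log2` scale; undetected
#'   cells become `NA`.
#' @export
log_transform <- function(x, base = 10) {
  if (!base %in% c(10, 2)) stop("base must be 10 or 2")
  if (x$scale != "linear") stop("matrix is already on a log scale")
  vn <- values_na(x)
  if (any(vn <= 0, na.rm = TRUE))
    stop("non-positive detected value; cannot log-transform")
  v <- log(vn, base = base)
  expr_matrix(v, x$design,
              scale = if (base == 10) "log10" else "log2",
              modality = x$modality, detected = x$detected)
}

#' Normalization report
#'
#' Bookkeeping record of feature counts and per-sample size factors
#' along the normalization pipeline.
#'
#' @param n_input_features,n_after_min_detection,n_constitutive integer
#'   feature counts (later entries may be `NA` until that step runs).
#' @param size_factors named positive numeric vector (transcript track).
#' @param quantile_reference numeric vector of reference order
#'   statistics.
#' @return An object of class `normalization_report`.
#' @export
normalization_report <- function(n_input_features = NA_integer_,
                                 n_after_min_detection = NA_integer_,
                                 n_constitutive = NA_integer_,
                                 size_factors = NULL,
                                 quantile_reference = NULL) {
  if (!is.null(size_factors) && any(size_factors <= 0))
    stop("size factors must be positive")
  structure(
    list(n_input_features = as.integer(n_input_features),
         n_after_min_detection = as.integer(n_after_min_detection),
         n_constitutive = as.integer(n_constitutive),
         size_factors = size_factors,
         quantile_reference = quantile_reference),
    class = "normalization_report"
  )
}

#' @export
print.normalization_report <- function(x, ...) {
  cat("normalization_report\n")
  cat("  input features:        ", x$n_input_features, "\n")
  cat("  after min-detection:   ", x$n_after_min_detection, "\n")
  cat("  constitutive:          ", x$n_constitutive, "\n")
  if (!is.null(x$size_factors))
    cat("  size factors:          ",
        paste(formatC(x$size_factors, digits = 4), collapse = " "), "\n")
  invisible(x)
}

## internal: median-of-ratios size factors, geometric-mean anchored
.size_factors <- function(counts) {
  lg <- log(counts)
  lg[!is.finite(lg)] <- NA_real_
  ref <- rowMeans(lg)               # log geometric mean; NA if any zero
  use <- is.finite(ref)
  if (!any(use))
    stop("no feature has positive counts in all samples; ",
         "add a pseudocount or filter samples")
  sf <- apply(lg[use, , drop = FALSE] - ref[use], 2L,
              stats::median, na.rm = TRUE)
  exp(sf)
}

#' Library-size normalization and log transform for counts
#'
#' Median-of-ratios size factors (each sample's factor is the median,
#' over features with all-positive counts, of the ratio of its count to
#' the feature's geometric mean), followed by `log2(count / sf + 1)`.
#' This is a deliberately simple stand-in for a regularized log
#' transform: it stabilizes library-size differences but applies no
#' variance shrinkage of low counts beyond the +1 shift.
#'
#' @param x linear-scale transcript [expr_matrix()] of non-negative
#'   integer counts.
#' @return A list with `matrix` (log2-scale `expr_matrix`) and `report`
#'   (a [normalization_report()] carrying the size factors).
#' @export
normalize_counts <- function(x) {
  if (x$scale != "linear") stop("normalize_counts needs raw counts")
  sf <- .size_factors(x$values)
  names(sf) <- colnames(x$values)
  v <- log2(sweep(x$values, 2L, sf, "/") + 1)
  v[!x$detected] <- NA_real_
  out <- expr_matrix(v, x$design, scale = "log2",
                     modality = x$modality, detected = x$detected)
  rep <- normalization_report(n_input_features = nrow(x$values),
                              size_factors = sf)
  list(matrix = out, report = rep)
}
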