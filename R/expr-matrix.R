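#' @keywords internal
"_PACKAGE"

## Fixed vocabularies of the experimental design: seven ordered developmental
## stages, two ovulation treatments.
STAGES <- c("oocyte", "1-cell", "2-cell", "4-cell", "8-cell",
            "morula", "blastocyst")
TREATMENTS <- c("superovulation", "natural")

#' Ordered developmental stages
#'
#' The seven stages of the oocyte-to-blastocyst series, in developmental
#' order. All stage fields throughout the package are validated against
#' this vocabulary.
#'
#' @return Character vector of the seven stage names.
#' @export
stage_levels <- function() STAGES

#' Treatment levels
#'
#' @return Character vector `c("superovulation", "natural")`.
#' @export
treatment_levels <- function() TREATMENTS

#' Construct a sample design table
#'
#' Validates per-sample metadata: unique sample ids, stages from the fixed
#' seven-stage vocabulary, treatments from
#' `c("superovulation", "natural")`, positive integer replicates.
#'
#' @param sample_id character vector of unique sample identifiers.
#' @param stage character vector of developmental stages (see
#'   [stage_levels()]).
#' @param treatment character vector of treatments (see
#'   [treatment_levels()]).
#' @param replicate positive integer vector of replicate indices.
#' @return A `data.frame` of class `sample_design` with columns
#'   `sample_id`, `stage` (ordered factor), `treatment` (factor),
#'   `replicate`.
#' @export
sample_design <- function(sample_id, stage, treatment, replicate) {
  sample_id <- as.character(sample_id)
  if (anyDuplicated(sample_id))
    stop("duplicated sample_id: ",
         paste(unique(sample_id[duplicated(sample_id)]), collapse = ", "))
  bad <- setdiff(unique(as.character(stage)), STAGES)
  if (length(bad))
    stop("unknown stage(s): ", paste(bad, collapse = ", "))
  bad <- setdiff(unique(as.character(treatment)), TREATMENTS)
  if (length(bad))
    stop("unknown treatment(s): ", paste(bad, collapse = ", "))
  replicate <- as.integer(replicate)
  if (any(is.na(replicate)) || any(replicate < 1))
    stop("replicate must be a positive integer")
  d <- data.frame(
    sample_id = sample_id,
    stage = factor(stage, levels = STAGES, ordered = TRUE),
    treatment = factor(treatment, levels = TREATMENTS),
    replicate = replicate,
    stringsAsFactors = FALSE
  )
  class(d) <- c("sample_design", "data.frame")
  d
}

#' Construct an expression matrix
#'
#' The central container of the package: a features-by-samples numeric
#' matrix with an explicit detection mask, a scale tag and a modality tag.
#' On the linear scale, detection is defined as value strictly greater than
#' zero: undetected cells are stored as 0. On log scales undetected cells
#' are stored as `NA`.
#'
#' @param values numeric matrix, features in rows, samples in columns.
#'   Row names are feature ids; column names must match
#'   `design$sample_id`.
#' @param design a [sample_design()] table, one row per column of
#'   `values`.
#' @param scale one of `"linear"`, `"log10"`, `"log2"`.
#' @param modality one of `"protein"`, `"transcript"`.
#' @param detected optional logical matrix, same shape as `values`.
#'   Defaults to `values > 0` (linear) or `!is.na(values)` (log).
#' @return An object of class `expr_matrix`: a list with elements
#'   `values`, `detected`, `design`, `scale`, `modality`.
#' @export
expr_matrix <- function(values, design,
                        scale = c("linear", "log10", "log2"),
                        modality = c("protein", "transcript"),
                        detected = NULL) {
  scale <- match.arg(scale)
  modality <- match.arg(modality)
  values <- as.matrix(values)
  if (is.null(rownames(values))) {
    if (nrow(values) == 0L) rownames(values) <- character(0)
    else stop("values must have feature ids as row names")
  }
  if (anyDuplicated(rownames(values)))
    stop("duplicated feature id: ",
         rownames(values)[duplicated(rownames(values))][1L])
  if (!inherits(design, "sample_design"))
    design <- sample_design(design$sample_id, design$stage,
                            design$treatment, design$replicate)
  if (ncol(values) != nrow(design))
    stop("design has ", nrow(design), " samples but values has ",
         ncol(values), " columns")
  if (is.null(colnames(values))) {
    colnames(values) <- design$sample_id
  } else if (!identical(colnames(values), design$sample_id)) {
    if (!setequal(colnames(values), design$sample_id))
      stop("column names of values do not match design sample ids")
    values <- values[, design$sample_id, drop = FALSE]
  }
  if (is.null(detected)) {
    detected <- if (scale == "linear") !is.na(values) & values > 0
                else !is.na(values)
  }
  detected <- as.matrix(detected)
  dimnames(detected) <- dimnames(values)
  if (scale == "linear") {
    values[!detected] <- 0
    if (any(values[detected] <= 0, na.rm = TRUE))
      stop("linear-scale detected values must be > 0")
  } else {
    values[!detected] <- NA_real_
  }
  if (any(!is.finite(values[detected])))
    stop("detected values must be finite")
  structure(
    list(values = values, detected = detected, design = design,
         scale = scale, modality = modality),
    class = "expr_matrix"
  )
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expr_matrix: %d %s feature(s) x %d sample(s) [%s scale]\n",
              nrow(x$values), x$modality, ncol(x$values), x$scale))
  det <- mean(x$detected)
  cat(sprintf("  detected cells: %.1f%%\n", 100 * det))
  cat(sprintf("  stages: %s\n",
              paste(levels(droplevels(x$design$stage)), collapse = ", ")))
  invisible(x)
}

#' @export
dim.expr_matrix <- function(x) dim(x$values)

#' Feature ids of an expression matrix
#' @param x an `expr_matrix`.
#' @return Character vector of feature ids.
#' @export
feature_ids <- function(x) rownames(x$values)

#' Values with undetected cells as NA
#'
#' @param x an `expr_matrix`.
#' @return Numeric matrix equal to `x$values` with `NA` at undetected
#'   cells, regardless of scale.
#' @export
values_na <- function(x) {
  v <- x$values
  v[!x$detected] <- NA_real_
  v
}

#' Subset an expression matrix by feature and/or sample
#'
#' @param x an `expr_matrix`.
#' @param features character vector of feature ids or logical/integer index.
#' @param samples character vector of sample ids or logical/integer index.
#' @return A new `expr_matrix`.
#' @export
subset_features <- function(x, features = NULL, samples = NULL) {
  fi <- if (is.null(features)) seq_len(nrow(x$values)) else features
  si <- if (is.null(samples)) seq_len(ncol(x$values)) else samples
  if (is.character(si)) si <- match(si, x$design$sample_id)
  d <- x$design[si, , drop = FALSE]
  class(d) <- c("sample_design", "data.frame")
  expr_matrix(x$values[fi, si, drop = FALSE], d,
              scale = x$scale, modality = x$modality,
              detected = x$detected[fi, si, drop = FALSE])
}

## internal: key "stage|treatment" per sample
.cell_key <- function(design) {
  paste(as.character(design$stage), as.character(design$treatment),
        sep = "|")
}

## internal: stop unless every (stage, treatment) cell that `stages`
## requires is present in the design
.check_full_design <- function(design, stages = STAGES) {
  need <- as.vector(outer(stages, TREATMENTS, paste, sep = "|"))
  have <- unique(.cell_key(design))
  miss <- setdiff(need, have)
  if (length(miss))
    stop("design is missing (stage, treatment) cell(s): ",
         paste(gsub("\\|", ", ", miss), collapse = "; "))
  invisible(TRUE)
}
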