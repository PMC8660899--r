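#' Pearson correlation distance between samples
#'
#' `d(a, b) = 1 - r(a, b)` with `r` the Pearson correlation between the
#' expression values of two samples over features; symmetric with a zero
#' diagonal.
#'
#' @param x an [expr_matrix()] with all cells detected (expression
#'   values).
#' @return A symmetric samples-by-samples distance matrix.
#' @export
correlation_distance_matrix <- function(x) {
  v <- values_na(x)
  if (anyNA(v))
    stop("correlation distances need fully detected values; ",
         "filter or average first")
  sds <- apply(v, 2L, stats::sd)
  if (any(sds == 0))
    stop("constant sample vector(s): ",
         paste(colnames(v)[sds == 0], collapse = ", "))
  d <- 1 - stats::cor(v)
  diag(d) <- 0
  d
}

#' Complete-linkage hierarchical clustering
#'
#' Agglomerative clustering via `stats::hclust(method = "complete")` on
#' a precomputed distance matrix.
#'
#' @param distances symmetric numeric distance matrix with dimnames, or
#'   a `dist` object.
#' @return An `hclust` object (n - 1 merges for n samples).
#' @export
hierarchical_cluster <- function(distances) {
  if (!inherits(distances, "dist")) {
    distances <- as.matrix(distances)
    if (anyNA(distances)) stop("NA distance")
    distances <- stats::as.dist(distances)
  }
  if (anyNA(distances)) stop("NA distance")
  stats::hclust(distances, method = "complete")
}

#' Heatmap row order of features
#'
#' Orders features by the leaf order of a complete-linkage tree on
#' pairwise Euclidean feature-feature distances.
#'
#' @param x an [expr_matrix()].
#' @return Character vector: a permutation of the feature ids.
#' @export
order_features <- function(x) {
  v <- values_na(x)
  v[is.na(v)] <- 0
  if (nrow(v) < 2L) return(rownames(v))
  hc <- stats::hclust(stats::dist(v), method = "complete")
  ## canonical leaf order: at every internal node the subtree whose
  ## smallest label sorts first comes first, so the order does not
  ## depend on the input row order
  walk <- function(node) {
    if (node < 0) return(hc$labels[-node])
    a <- walk(hc$merge[node, 1L])
    b <- walk(hc$merge[node, 2L])
    if (min(a) <= min(b)) c(a, b) else c(b, a)
  }
  walk(nrow(hc$merge))
}

#' Principal component analysis of samples
#'
#' SVD of the feature-centered matrix with samples as observations
#' (centered, unscaled by default). Variance fractions are
#' `sigma_k^2 / sum(sigma^2)`.
#'
#' @param x an [expr_matrix()] with all cells detected.
#' @param center,scale. passed to `stats::prcomp`.
#' @return An object of class `expr_pca`: list with `scores` (samples x
#'   components), `loadings` (features x components),
#'   `variance_fraction`, and the `design`.
#' @export
pca_samples <- function(x, center = TRUE, scale. = FALSE) {
  v <- t(values_na(x))
  if (anyNA(v)) stop("PCA needs fully detected values")
  if (all(apply(v, 2L, stats::sd) == 0))
    stop("all features are constant")
  pc <- stats::prcomp(v, center = center, scale. = scale.)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  structure(
    list(scores = pc$x, loadings = pc$rotation,
         variance_fraction = vf, design = x$design),
    class = "expr_pca"
  )
}

#' @export
print.expr_pca <- function(x, ...) {
  k <- min(6L, length(x$variance_fraction))
  cat("expr_pca:", nrow(x$scores), "samples\n")
  cat("  variance fractions:",
      paste(sprintf("PC%d %.1f%%", seq_len(k),
                    100 * x$variance_fraction[seq_len(k)]),
            collapse = ", "), "\n")
  invisible(x)
}

#' Which principal component separates the treatments?
#'
#' A component "separates" when a scalar threshold puts all
#' superovulation scores strictly on one side of all natural-ovulation
#' scores (strict linear separability on that axis). The point-biserial
#' correlation between scores and the treatment indicator is reported
#' alongside, because perfect separation is brittle at small sample
#' sizes.
#'
#' @param pca an `expr_pca` from [pca_samples()].
#' @param design optional [sample_design()] (defaults to the design
#'   stored in `pca`).
#' @param n_components number of leading components to assess (default
#'   all).
#' @return An object of class `treatment_separation`: a data.frame with
#'   columns `component`, `variance_fraction`, `separates`,
#'   `point_biserial_r`, plus attribute `first_separating` (the
#'   smallest separating component index, or `NA`).
#' @export
treatment_separation <- function(pca, design = pca$design,
                                 n_components = NULL) {
  tr <- design$treatment
  if (length(unique(tr)) < 2L)
    stop("both treatment groups must be present")
  k <- ncol(pca$scores)
  if (!is.null(n_components)) k <- min(k, n_components)
  ind <- as.numeric(tr == "superovulation")
  sep <- logical(k)
  r <- numeric(k)
  for (j in seq_len(k)) {
    s <- pca$scores[, j]
    a <- s[ind == 1]
    b <- s[ind == 0]
    sep[j] <- max(a) < min(b) || max(b) < min(a)
    r[j] <- suppressWarnings(stats::cor(s, ind))
  }
  out <- data.frame(component = seq_len(k),
                    variance_fraction = pca$variance_fraction[seq_len(k)],
                    separates = sep,
                    point_biserial_r = r)
  attr(out, "first_separating") <-
    if (any(sep)) min(which(sep)) else NA_integer_
  class(out) <- c("treatment_separation", "data.frame")
  out
}

#' @export
print.treatment_separation <- function(x, ...) {
  fs <- attr(x, "first_separating")
  cat("treatment_separation:",
      if (is.na(fs)) "no component separates the treatments"
      else sprintf("first separating component = PC%d (%.1f%% variance)",
                   fs, 100 * x$variance_fraction[fs]), "\n")
  print.data.frame(utils::head(x, 8L), row.names = FALSE, digits = 3)
  invisible(x)
}
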