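#' Oocyte diameter from perimeter
#'
#' The ooplasm is traced along the oolemma in the equatorial section;
#' the diameter of the (approximately spherical) oocyte proper is the
#' perimeter divided by pi.
#'
#' @param perimeter perimeter in micrometers (> 0).
#' @return Diameter in micrometers.
#' @export
diameter_from_perimeter <- function(perimeter) {
  if (any(perimeter <= 0)) stop("perimeter must be positive")
  perimeter / pi
}

#' Sphere volume in picoliters
#'
#' Spherical approximation of the ooplasm volume:
#' `V = (4/3) * pi * (d/2)^3` cubic micrometers, converted at
#' 1 pL = 1000 um^3.
#'
#' @param diameter diameter in micrometers (> 0).
#' @return Volume in picoliters.
#' @export
sphere_volume_pl <- function(diameter) {
  if (any(diameter <= 0)) stop("diameter must be positive")
  (4 / 3) * pi * (diameter / 2)^3 / 1000
}

## internal: validate a k x 2 count table
.check_table <- function(tab, square = FALSE) {
  tab <- as.matrix(tab)
  if (any(tab < 0) || any(tab != round(tab)))
    stop("counts must be non-negative integers")
  if (ncol(tab) != 2L || (square && nrow(tab) != 2L))
    stop("table must be ", if (square) "2 x 2" else "k x 2")
  if (any(rowSums(tab) == 0) || any(colSums(tab) == 0))
    stop("zero row or column margin")
  tab
}

#' Fisher's exact test for a 2 x 2 table
#'
#' Two-sided p by probability-mass summation over the conditional
#' hypergeometric distribution (all tables with probability at most
#' the observed table's, within a 1e-7 relative tolerance), plus the
#' sample odds ratio `ad/bc` (0 and Inf allowed).
#'
#' @param tab 2 x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @return List with `odds_ratio` and `p_value`.
#' @export
fisher_exact_2x2 <- function(tab) {
  tab <- .check_table(tab, square = TRUE)
  ft <- stats::fisher.test(tab)
  or <- (tab[1, 1] * tab[2, 2]) / (tab[1, 2] * tab[2, 1])
  list(odds_ratio = or, p_value = ft$p.value)
}

#' Two-sample Wilcoxon rank-sum test
#'
#' Exact enumeration of the rank-sum distribution for small untied
#' samples (`n_x + n_y <= threshold` and no ties), tie-corrected normal
#' approximation (no continuity correction) otherwise; the mode used is
#' recorded in the output.
#'
#' @param x,y numeric vectors (both non-empty).
#' @param mode `"auto"`, `"exact"` or `"normal_approx"`.
#' @param exact_threshold maximum total sample size for the automatic
#'   exact mode (default 12).
#' @return List with `p_value`, `statistic` (rank-sum W of `x`) and
#'   `mode`.
#' @export
wilcoxon_rank_sum <- function(x, y,
                              mode = c("auto", "exact", "normal_approx"),
                              exact_threshold = 12L) {
  mode <- match.arg(mode)
  if (!length(x) || !length(y)) stop("both groups must be non-empty")
  ties <- anyDuplicated(c(x, y)) > 0L
  if (mode == "auto")
    mode <- if (!ties && length(x) + length(y) <= exact_threshold)
      "exact" else "normal_approx"
  if (mode == "exact" && ties)
    stop("exact mode is undefined with ties; use normal_approx")
  wt <- suppressWarnings(
    stats::wilcox.test(x, y, exact = mode == "exact",
                       correct = FALSE)
  )
  list(p_value = wt$p.value, statistic = unname(wt$statistic),
       mode = mode)
}

#' Chi-square test of homogeneity for a k x 2 table
#'
#' Pearson's `X^2 = sum (O - E)^2 / E` with `df = k - 1`, upper-tail
#' chi-square p, no continuity correction by default. Warns when an
#' expected count falls below 5.
#'
#' @param tab k x 2 matrix of non-negative integer counts with positive
#'   margins.
#' @param correct apply the Yates continuity correction (2 x 2 only;
#'   default `FALSE`).
#' @return List with `statistic`, `df`, `p_value`.
#' @export
chi_square_homogeneity <- function(tab, correct = FALSE) {
  tab <- .check_table(tab)
  expected <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  if (any(expected < 5))
    warning("expected count(s) below 5; chi-square approximation ",
            "may be poor")
  ct <- suppressWarnings(stats::chisq.test(tab, correct = correct))
  list(statistic = unname(ct$statistic), df = unname(ct$parameter),
       p_value = ct$p.value)
}
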