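## Exact sign-flip permutation inference on the Wilcoxon signed-rank
## statistic. The observed statistic is T = sum(sign(d_i) * rank(|d_i|))
## over nonzero paired differences; its exact null distribution is
## obtained by enumerating all 2^n sign assignments on the fixed ranks.
## Enumeration is done by subset-sum convolution over doubled ranks
## (doubling makes mid-ranks integral), cached per rank multiset, so
## thousands of features sharing the tie-free rank vector 1..n reuse one
## distribution.

.perm_cache <- new.env(parent = emptyenv())

## ranks of |d| after the zero policy; returns list(ranks, signs)
.signed_ranks <- function(d, zero_policy = c("exclude", "pratt")) {
  zero_policy <- match.arg(zero_policy)
  d <- d[!is.na(d)]
  if (zero_policy == "exclude") {
    d <- d[d != 0]
    if (!length(d)) return(list(ranks = numeric(0), signs = numeric(0)))
    list(ranks = rank(abs(d)), signs = sign(d))
  } else {
    if (!length(d)) return(list(ranks = numeric(0), signs = numeric(0)))
    r <- rank(abs(d))
    keep <- d != 0
    list(ranks = r[keep], signs = sign(d)[keep])
  }
}

#' Wilcoxon signed-rank statistic
#'
#' `T = sum(sign(d_i) * rank(|d_i|))` with mid-ranks for ties. Zero
#' differences are dropped before ranking (`"exclude"`, the classical
#' convention) or ranked but excluded from the sum (`"pratt"`).
#'
#' @param d numeric vector of paired differences (NAs ignored).
#' @param zero_policy `"exclude"` or `"pratt"`.
#' @return The signed-rank statistic (0 for an all-zero vector).
#' @export
signed_rank_statistic <- function(d, zero_policy = c("exclude", "pratt")) {
  sr <- .signed_ranks(d, zero_policy)
  if (!length(sr$ranks)) return(0)
  sum(sr$signs * sr$ranks)
}

## distribution of W = sum of doubled ranks assigned "+", as cumulative
## counts; cached by rank multiset
.subset_sum_counts <- function(w) {
  key <- paste(sort(w), collapse = ",")
  hit <- .perm_cache[[key]]
  if (!is.null(hit)) return(hit)
  S <- sum(w)
  cnt <- numeric(S + 1L)
  cnt[1L] <- 1
  for (wi in w) {
    shifted <- c(numeric(wi), cnt[seq_len(S + 1L - wi)])
    cnt <- cnt + shifted
  }
  out <- list(cnt = cnt, cum = cumsum(cnt), S = S,
              total = 2^length(w))
  assign(key, out, envir = .perm_cache)
  out
}

#' Exact permutation p-value for the signed-rank statistic
#'
#' Two-sided exact sign-flip test: all `2^n` assignments of signs to the
#' ranked absolute differences are enumerated and
#' `p = #\{|T*| >= |T_obs|\} / 2^n`. With no nonzero difference the
#' p-value is 1. The attainable minimum is `2 / 2^n` (n = 7 stage pairs
#' gives 0.015625; n = 14 stage-replicate pairs gives ~1.22e-4).
#'
#' @param d numeric vector of paired differences (NAs ignored).
#' @param zero_policy `"exclude"` or `"pratt"` (see
#'   [signed_rank_statistic()]).
#' @param max_n maximum number of nonzero differences for full
#'   enumeration (default 20); beyond it an error directs to explicit
#'   subsampling rather than silently approximating.
#' @return p-value in (0, 1].
#' @export
exact_permutation_pvalue <- function(d,
                                     zero_policy = c("exclude", "pratt"),
                                     max_n = 20L) {
  sr <- .signed_ranks(d, zero_policy)
  n <- length(sr$ranks)
  if (n == 0L) return(1)
  if (n > max_n)
    stop("n = ", n, " nonzero differences exceeds the enumeration ",
         "bound (", max_n, "); reduce pairs or opt into Monte-Carlo ",
         "sampling explicitly")
  w <- as.integer(round(2 * sr$ranks))
  t_obs <- abs(sum(sr$signs * w))            # doubled scale
  if (t_obs == 0L) return(1)                 # every |T*| >= 0
  dist <- .subset_sum_counts(w)
  S <- dist$S
  ## |2W - S| >= t_obs  <=>  W >= (S + t_obs)/2  or  W <= (S - t_obs)/2
  hi <- ceiling((S + t_obs) / 2)
  lo <- floor((S - t_obs) / 2)
  n_hi <- dist$cum[S + 1L] - if (hi >= 1L) dist$cum[hi] else 0
  n_lo <- if (lo >= 0L) dist$cum[lo + 1L] else 0
  (n_hi + n_lo) / dist$total
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate q-values via `stats::p.adjust`.
#'
#' @param p numeric vector of p-values in \[0, 1\].
#' @return q-values, same order as `p`.
#' @export
bh_adjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

## internal: features x stages matrix of paired differences
## (superovulation - natural), NA where either side is undetected
.paired_differences <- function(x, pairing = c("stage", "stage_replicate")) {
  pairing <- match.arg(pairing)
  vn <- values_na(x)
  des <- x$design
  if (pairing == "stage") {
    key <- .cell_key(des)
    if (anyDuplicated(key)) {
      x <- average_replicates(x)
      vn <- values_na(x)
      des <- x$design
    }
    cols <- function(tr) {
      idx <- match(paste(STAGES, tr, sep = "|"), .cell_key(des))
      vn[, idx, drop = FALSE]
    }
    d <- cols("superovulation") - cols("natural")
    colnames(d) <- STAGES
  } else {
    key <- paste(as.character(des$stage), des$replicate, sep = "|")
    so <- des$treatment == "superovulation"
    shared <- intersect(unique(key[so]), unique(key[!so]))
    if (!length(shared))
      stop("no (stage, replicate) pair present in both treatments")
    so_idx <- match(shared, ifelse(so, key, NA))
    na_idx <- match(shared, ifelse(!so, key, NA))
    d <- vn[, so_idx, drop = FALSE] - vn[, na_idx, drop = FALSE]
    colnames(d) <- gsub("|", ".r", shared, fixed = TRUE)
  }
  rownames(d) <- rownames(vn)
  d
}

#' Stage-paired exact permutation differential-expression test
#'
#' For every feature, expression values are paired across treatments —
#' one difference per developmental stage (`pairing = "stage"`, after
#' replicate averaging; 7 pairs) or one per stage-replicate combination
#' (`pairing = "stage_replicate"`; up to 14 pairs) — and the treatment
#' contrast is tested with a two-sided exact sign-flip permutation test
#' on the Wilcoxon signed-rank statistic. P-values are adjusted with
#' Benjamini-Hochberg across all tested features; a feature is called
#' significant when `q < alpha_fdr`.
#'
#' Features with fewer than two complete pairs are reported with
#' `p = 1` and flagged (`insufficient_pairs`), never dropped silently.
#'
#' @param x normalized log-scale [expr_matrix()] (the "expression
#'   values"), restricted to the feature set to be tested (typically the
#'   constitutive set).
#' @param pairing `"stage"` or `"stage_replicate"`.
#' @param alpha_fdr FDR threshold for the significance call (default
#'   0.1).
#' @param zero_policy zero-difference handling, see
#'   [signed_rank_statistic()].
#' @param fc_matrix optional linear-scale replicate-averaged
#'   `expr_matrix` (same features) from which per-stage fold changes
#'   superovulation/natural are computed.
#' @return An object of class `paired_de`: list with `results` (a
#'   data.frame with columns `feature_id`, `n_pairs`, `statistic`,
#'   `p_value`, `q_value`, `significant`, `insufficient_pairs`,
#'   `max_abs_fc`, `direction`), `fold_changes` (features x stages
#'   linear ratios, or NULL), and the call parameters.
#' @export
paired_de_test <- function(x, pairing = c("stage", "stage_replicate"),
                           alpha_fdr = 0.1,
                           zero_policy = c("exclude", "pratt"),
                           fc_matrix = NULL) {
  pairing <- match.arg(pairing)
  zero_policy <- match.arg(zero_policy)
  .check_full_design(x$design)
  d <- .paired_differences(x, pairing)
  nf <- nrow(d)
  n_pairs <- rowSums(!is.na(d))
  stat <- numeric(nf)
  p <- rep(1, nf)
  for (i in seq_len(nf)) {
    if (n_pairs[i] < 2L) next
    di <- d[i, ]
    stat[i] <- signed_rank_statistic(di, zero_policy)
    p[i] <- exact_permutation_pvalue(di, zero_policy)
  }
  q <- bh_adjust(p)
  fc <- NULL
  max_abs_fc <- rep(NA_real_, nf)
  direction <- rep("none", nf)
  if (!is.null(fc_matrix)) {
    fc <- .stage_fold_changes(fc_matrix)
    fc <- fc[rownames(d), , drop = FALSE]
    ext <- pmax(fc, 1 / fc)
    max_abs_fc <- apply(ext, 1L, function(z)
      if (all(is.na(z))) NA_real_ else max(z, na.rm = TRUE))
    med <- apply(log(fc), 1L, stats::median, na.rm = TRUE)
    direction <- ifelse(is.na(med) | med == 0, "none",
                        ifelse(med > 0, "up", "down"))
  }
  res <- data.frame(
    feature_id = rownames(d),
    n_pairs = n_pairs,
    statistic = stat,
    p_value = p,
    q_value = q,
    significant = q < alpha_fdr,
    insufficient_pairs = n_pairs < 2L,
    max_abs_fc = max_abs_fc,
    direction = direction,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  structure(
    list(results = res, fold_changes = fc, differences = d,
         pairing = pairing, alpha_fdr = alpha_fdr,
         zero_policy = zero_policy),
    class = "paired_de"
  )
}

#' @export
print.paired_de <- function(x, ...) {
  r <- x$results
  cat(sprintf(
    "paired_de: %d feature(s), %s pairing, exact permutation test\n",
    nrow(r), x$pairing))
  cat(sprintf("  significant at FDR < %s: %d\n", x$alpha_fdr,
              sum(r$significant)))
  if (any(r$insufficient_pairs))
    cat(sprintf("  flagged (fewer than 2 complete pairs): %d\n",
                sum(r$insufficient_pairs)))
  invisible(x)
}

#' @export
summary.paired_de <- function(object, fc_cut = 2, ...) {
  r <- object$results
  ud <- classify_up_down(object, fc_cut = fc_cut)
  out <- list(
    n_features = nrow(r),
    pairing = object$pairing,
    alpha_fdr = object$alpha_fdr,
    n_significant = sum(r$significant),
    min_p = min(r$p_value),
    fc_cut = fc_cut,
    n_up = ud[["n_up"]],
    n_down = ud[["n_down"]]
  )
  class(out) <- "summary.paired_de"
  out
}

#' @export
print.summary.paired_de <- function(x, ...) {
  cat(sprintf("Stage-paired permutation DE (%s pairing)\n", x$pairing))
  cat(sprintf("  features tested:               %d\n", x$n_features))
  cat(sprintf("  significant (BH FDR < %s):     %d\n", x$alpha_fdr,
              x$n_significant))
  cat(sprintf("  of which > %s-fold:             up %d, down %d\n",
              x$fc_cut, x$n_up, x$n_down))
  cat(sprintf("  smallest attained p:           %.3g\n", x$min_p))
  invisible(x)
}

## internal: features x stages matrix of linear fold changes SO/NAT
## from a replicate-averaged linear matrix; NA where either treatment
## is undetected at that stage
.stage_fold_changes <- function(x) {
  if (x$scale != "linear")
    stop("fold changes are computed on a linear-scale matrix")
  key <- .cell_key(x$design)
  if (anyDuplicated(key)) x <- average_replicates(x)
  vn <- values_na(x)
  key <- .cell_key(x$design)
  so <- vn[, match(paste(STAGES, "superovulation", sep = "|"), key),
           drop = FALSE]
  na <- vn[, match(paste(STAGES, "natural", sep = "|"), key),
           drop = FALSE]
  fc <- so / na
  dimnames(fc) <- list(rownames(vn), STAGES)
  fc
}

#' Stage-wise fold-change census
#'
#' Counts, per stage and per threshold, the features whose linear fold
#' change between the two treatments (in either direction:
#' `max(FC, 1/FC)`) is greater than or equal to the threshold. Features
#' undetected in one treatment at a stage are excluded from that
#' stage's census (no infinite fold changes).
#'
#' @param x linear-scale [expr_matrix()], replicate-averaged (averaged
#'   automatically if replicate columns are present).
#' @param thresholds numeric thresholds (default `c(4, 5, 6, 7, 8)`).
#' @return An integer matrix, stages x thresholds.
#' @export
fold_change_census <- function(x, thresholds = c(4, 5, 6, 7, 8)) {
  fc <- .stage_fold_changes(x)
  ext <- pmax(fc, 1 / fc)
  out <- sapply(thresholds, function(t)
    colSums(ext >= t, na.rm = TRUE))
  out <- matrix(as.integer(out), nrow = length(STAGES),
                dimnames = list(STAGES, paste0("fc_ge_", thresholds)))
  out
}

#' Count up- and downregulated features
#'
#' Among the significant features of a [paired_de_test()], counts those
#' whose largest stage fold change strictly exceeds `fc_cut` ("in
#' excess of" the cutoff), split by direction (sign of the median stage
#' log fold change).
#'
#' @param de a `paired_de` object fitted with a `fc_matrix`.
#' @param fc_cut fold-change cutoff (default 2; strict `>`).
#' @return Named integer vector `c(n_up, n_down)`.
#' @export
classify_up_down <- function(de, fc_cut = 2) {
  r <- de$results
  sel <- r$significant & !is.na(r$max_abs_fc) & r$max_abs_fc > fc_cut
  c(n_up = sum(sel & r$direction == "up"),
    n_down = sum(sel & r$direction == "down"))
}

#' Abundance shift of a feature subset
#'
#' Tests whether a subset of features (e.g. the differentially expressed
#' set) is systematically more abundant than the rest of the proteome:
#' two-sample rank-sum test on per-feature mean log10 riBAQ, subset vs
#' complement, with the two empirical CDFs for plotting.
#'
#' @param x linear-scale [expr_matrix()] of riBAQ fractions.
#' @param subset_ids character vector of feature ids (a proper,
#'   non-empty subset of the features of `x`).
#' @return A list with `p_value`, `subset_mean`, `complement_mean`,
#'   `shift` (difference of means, log10 units), `ecdf_subset`,
#'   `ecdf_complement`.
#' @export
abundance_shift_check <- function(x, subset_ids) {
  ids <- feature_ids(x)
  if (!length(subset_ids)) stop("subset is empty")
  missing_ids <- setdiff(subset_ids, ids)
  if (length(missing_ids))
    stop("subset id(s) not in matrix: ",
         paste(utils::head(missing_ids, 3), collapse = ", "))
  if (length(subset_ids) >= length(ids))
    stop("subset must be a proper subset of the features")
  mlog <- rowMeans(log10(values_na(x)), na.rm = TRUE)
  a <- mlog[ids %in% subset_ids]
  b <- mlog[!ids %in% subset_ids]
  p <- wilcoxon_rank_sum(a, b)$p_value
  list(p_value = p,
       subset_mean = mean(a), complement_mean = mean(b),
       shift = mean(a) - mean(b),
       ecdf_subset = stats::ecdf(a), ecdf_complement = stats::ecdf(b))
}
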