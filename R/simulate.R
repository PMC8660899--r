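## internal: evaluate expr with a local RNG seed, restoring the global
## RNG state afterwards
.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv()))
      rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulation configuration
#'
#' Parameters of the synthetic proteome/transcriptome generator, which
#' emulates the study design: 7 ordered stages x 2 treatments x
#' `n_replicates` replicate pools, log10-scale abundances with a shared
#' developmental trajectory (flat drift before the morula, then a
#' regime shift at morula/blastocyst), a treatment effect on a random
#' feature subset whose stage profile peaks at the 8-cell stage and is
#' smallest at the blastocyst, abundance-dependent logistic detection
#' dropout, and a high-abundance bias of the affected features. The
#' transcript track shares the stage trajectory shape but generates
#' negative-binomial counts with (by default) a zero treatment effect.
#'
#' @param n_features number of protein features (default 2000).
#' @param n_replicates replicate pools per (stage, treatment) (default
#'   2).
#' @param baseline_mean,baseline_sd per-feature baseline log10 riBAQ
#'   fraction, Normal (defaults -5, 1).
#' @param stage_curve length-7 shared trajectory (log10 units) each
#'   feature follows scaled by its own coefficient; the default is
#'   nearly flat over oocyte..8-cell with a jump at morula/blastocyst.
#' @param slope_sd sd of the per-feature trajectory coefficient
#'   (mean 0; default 1).
#' @param wiggle_sd sd of independent per-feature-per-stage wobble
#'   shared by treatments and replicates (default 0.03).
#' @param pi_de fraction of features carrying a treatment effect
#'   (default 0.1).
#' @param delta peak log10 treatment shift (default 0.6).
#' @param delta_profile length-7 relative stage profile of the shift,
#'   peaking at the 8-cell stage (default
#'   `c(0.5, 0.6, 0.75, 0.9, 1, 0.7, 0.4)`).
#' @param noise_sd replicate noise sd, log10 units (default 0.2).
#' @param dropout_a,dropout_b detection model
#'   `P(detect) = plogis(a + b * log10(abundance))` (defaults 10, 1.2).
#' @param de_abundance_weight strength of the bias of affected features
#'   toward high abundance (default 1; 0 = unbiased).
#' @param t_n_features,t_baseline_mean,t_baseline_sd transcript track:
#'   number of features and log10 mean-count distribution (defaults
#'   20000, 1.3, 0.8).
#' @param dispersion negative-binomial dispersion phi (variance
#'   `mu + phi mu^2`; default 0.05).
#' @param libsize_sd sd of log10 library-size factors (default 0.1).
#' @param delta_t transcript treatment effect (default 0: null
#'   contrast).
#' @param seed default integer seed echoed into outputs.
#' @return An object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_features = 2000L,
                       n_replicates = 2L,
                       baseline_mean = -5,
                       baseline_sd = 1,
                       stage_curve = c(-0.10, -0.07, -0.04, -0.01,
                                       0.02, 0.62, 0.80),
                       slope_sd = 1,
                       wiggle_sd = 0.03,
                       pi_de = 0.1,
                       delta = 0.6,
                       delta_profile = c(0.5, 0.6, 0.75, 0.9,
                                         1.0, 0.7, 0.4),
                       noise_sd = 0.2,
                       dropout_a = 10,
                       dropout_b = 1.2,
                       de_abundance_weight = 1,
                       t_n_features = 20000L,
                       t_baseline_mean = 1.3,
                       t_baseline_sd = 0.8,
                       dispersion = 0.05,
                       libsize_sd = 0.1,
                       delta_t = 0,
                       seed = 1L) {
  cfg <- as.list(environment())
  chk <- function(ok, field, msg)
    if (!ok) stop("invalid sim_config field '", field, "': ", msg)
  chk(cfg$n_features >= 1, "n_features", "must be >= 1")
  chk(cfg$n_replicates >= 1, "n_replicates", "must be >= 1")
  chk(length(cfg$stage_curve) == 7, "stage_curve", "needs 7 values")
  chk(length(cfg$delta_profile) == 7, "delta_profile", "needs 7 values")
  chk(cfg$pi_de >= 0 && cfg$pi_de <= 1, "pi_de", "must be in [0, 1]")
  chk(cfg$noise_sd > 0, "noise_sd", "must be > 0")
  chk(cfg$baseline_sd > 0, "baseline_sd", "must be > 0")
  chk(cfg$dispersion > 0, "dispersion", "must be > 0")
  chk(cfg$delta >= 0, "delta", "must be >= 0")
  structure(cfg, class = "sim_config")
}

## internal: the 7 x 2 x r design table
.sim_design <- function(n_replicates) {
  g <- expand.grid(replicate = seq_len(n_replicates),
                   treatment = TREATMENTS, stage = STAGES,
                   stringsAsFactors = FALSE)
  sample_design(
    sample_id = paste(g$stage, g$treatment, paste0("r", g$replicate),
                      sep = "_"),
    stage = g$stage, treatment = g$treatment, replicate = g$replicate
  )
}

## internal: draw the DE indicator with abundance bias
.draw_de <- function(baseline, pi_de, weight) {
  if (pi_de == 0) return(logical(length(baseline)))
  z <- (baseline - mean(baseline)) / stats::sd(baseline)
  p <- pi_de * exp(weight * z) / mean(exp(weight * z))
  stats::runif(length(baseline)) < pmin(1, p)
}

#' Generate a synthetic proteome
#'
#' Draws a linear-scale protein [expr_matrix()] under the design of
#' [sim_config()] together with its ground truth. Intensities are
#' `10^(baseline + trajectory + treatment shift + noise)`, zeroed where
#' the logistic abundance-dependent dropout marks them undetected.
#' Fully reproducible from the seed.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return List with `matrix` (linear protein `expr_matrix`) and
#'   `truth` (class `synthetic_truth`: data.frame `features` with
#'   `feature_id`, `is_de`, `sign`; matrix `true_lfc` of per-stage true
#'   log10 fold changes; the `config` and `seed`).
#' @export
generate_proteome <- function(config = sim_config(),
                              seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    des <- .sim_design(config$n_replicates)
    nf <- config$n_features
    ns <- nrow(des)
    ids <- sprintf("P%04d", seq_len(nf))
    baseline <- stats::rnorm(nf, config$baseline_mean,
                             config$baseline_sd)
    slope <- stats::rnorm(nf, 0, config$slope_sd)
    wiggle <- matrix(stats::rnorm(nf * 7L, 0, config$wiggle_sd),
                     nf, 7L)
    is_de <- .draw_de(baseline, config$pi_de,
                      config$de_abundance_weight)
    sgn <- ifelse(stats::runif(nf) < 0.5, 1, -1)
    sgn[!is_de] <- 0
    true_lfc <- outer(sgn * config$delta, config$delta_profile)
    dimnames(true_lfc) <- list(ids, STAGES)
    s_idx <- as.integer(des$stage)
    is_so <- des$treatment == "superovulation"
    mu <- outer(baseline, rep(1, ns)) +
      outer(slope, config$stage_curve[s_idx]) +
      wiggle[, s_idx, drop = FALSE] +
      sweep(true_lfc[, s_idx, drop = FALSE], 2L, as.numeric(is_so), "*")
    lg <- mu + matrix(stats::rnorm(nf * ns, 0, config$noise_sd), nf, ns)
    p_det <- stats::plogis(config$dropout_a + config$dropout_b * lg)
    det <- matrix(stats::runif(nf * ns) < p_det, nf, ns)
    v <- 10^lg
    v[!det] <- 0
    dimnames(v) <- list(ids, des$sample_id)
    dimnames(det) <- dimnames(v)
    m <- expr_matrix(v, des, scale = "linear", modality = "protein",
                     detected = det)
    truth <- structure(
      list(features = data.frame(feature_id = ids, is_de = is_de,
                                 sign = sgn, baseline = baseline,
                                 stringsAsFactors = FALSE),
           true_lfc = true_lfc, config = config, seed = seed),
      class = "synthetic_truth")
    list(matrix = m, truth = truth)
  })
}

#' Generate a synthetic transcriptome
#'
#' Negative-binomial count matrix sharing the proteome's stage
#' trajectory shape, with library-size factors and a (default zero)
#' treatment effect `delta_t` — the near-null transcriptome contrast of
#' the study design.
#'
#' @param config a [sim_config()].
#' @param seed integer seed (default `config$seed`).
#' @return List with `matrix` (linear transcript `expr_matrix` of
#'   counts) and `truth` (`synthetic_truth`, log2-free: `true_lfc` in
#'   log10 units like the proteome).
#' @export
generate_transcriptome <- function(config = sim_config(),
                                   seed = config$seed) {
  stopifnot(inherits(config, "sim_config"))
  .with_seed(seed, {
    des <- .sim_design(config$n_replicates)
    nf <- config$t_n_features
    ns <- nrow(des)
    ids <- sprintf("T%05d", seq_len(nf))
    baseline <- stats::rnorm(nf, config$t_baseline_mean,
                             config$t_baseline_sd)
    slope <- stats::rnorm(nf, 0, config$slope_sd)
    if (config$delta_t > 0) {
      is_de <- .draw_de(baseline, config$pi_de,
                        config$de_abundance_weight)
      sgn <- ifelse(stats::runif(nf) < 0.5, 1, -1)
      sgn[!is_de] <- 0
    } else {
      is_de <- logical(nf)
      sgn <- numeric(nf)
    }
    true_lfc <- outer(sgn * config$delta_t, config$delta_profile)
    dimnames(true_lfc) <- list(ids, STAGES)
    lib <- 10^stats::rnorm(ns, 0, config$libsize_sd)
    s_idx <- as.integer(des$stage)
    is_so <- des$treatment == "superovulation"
    lmu <- outer(baseline, rep(1, ns)) +
      outer(slope, config$stage_curve[s_idx]) +
      sweep(true_lfc[, s_idx, drop = FALSE], 2L, as.numeric(is_so), "*")
    mu <- sweep(10^lmu, 2L, lib, "*")
    v <- matrix(stats::rnbinom(nf * ns, mu = mu,
                               size = 1 / config$dispersion), nf, ns)
    dimnames(v) <- list(ids, des$sample_id)
    m <- expr_matrix(v, des, scale = "linear", modality = "transcript")
    truth <- structure(
      list(features = data.frame(feature_id = ids, is_de = is_de,
                                 sign = sgn, baseline = baseline,
                                 stringsAsFactors = FALSE),
           true_lfc = true_lfc, config = config, seed = seed),
      class = "synthetic_truth")
    list(matrix = m, truth = truth)
  })
}

#' Recovery metrics against simulation ground truth
#'
#' Compares the calls of a [paired_de_test()] with the generator's
#' truth: `sensitivity = TP / (TP + FN)` (true-DE features dropped by
#' upstream filters count as missed) and
#' `realized_fdr = FP / max(1, discoveries)` at `q < alpha`. When a
#' [fold_change_census()] table is supplied, the per-stage census error
#' (observed minus truth-implied counts) is reported as well.
#'
#' @param de a `paired_de` object.
#' @param truth a `synthetic_truth`.
#' @param alpha FDR threshold (default the test's `alpha_fdr`).
#' @param census optional stage x threshold census matrix.
#' @return List with `sensitivity`, `realized_fdr`, `tp`, `fp`, `fn`,
#'   `n_discoveries`, and (when `census` given) `census_error`.
#' @export
evaluate_recovery <- function(de, truth, alpha = de$alpha_fdr,
                              census = NULL) {
  r <- de$results
  unknown <- setdiff(r$feature_id, truth$features$feature_id)
  if (length(unknown))
    stop("feature id(s) not in truth: ",
         paste(utils::head(unknown, 3), collapse = ", "))
  is_de <- truth$features$is_de
  names(is_de) <- truth$features$feature_id
  called <- r$feature_id[r$q_value < alpha]
  tp <- sum(is_de[called])
  fp <- length(called) - tp
  fn <- sum(is_de) - tp
  out <- list(
    sensitivity = if (tp + fn == 0) NA_real_ else tp / (tp + fn),
    realized_fdr = fp / max(1, length(called)),
    tp = tp, fp = fp, fn = fn, n_discoveries = length(called)
  )
  if (!is.null(census)) {
    th <- as.numeric(sub("fc_ge_", "", colnames(census)))
    implied <- sapply(th, function(t)
      colSums(abs(truth$true_lfc) >= log10(t)))
    implied <- matrix(as.integer(implied), nrow = length(STAGES),
                      dimnames = dimnames(census))
    out$census_error <- census - implied
  }
  out
}
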