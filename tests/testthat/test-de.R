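test_that("signed-rank statistic handles signs, ties and zeros", {
  expect_equal(signed_rank_statistic(c(1, -2, 3)), 2)
  expect_equal(signed_rank_statistic(c(1, 1, 1)), 6)
  expect_equal(signed_rank_statistic(c(0, 0)), 0)
  # Pratt keeps zero ranks in the pool
  expect_equal(signed_rank_statistic(c(0, 1), zero_policy = "pratt"), 2)
  expect_equal(signed_rank_statistic(c(0, 1), zero_policy = "exclude"), 1)
})

test_that("exact permutation p matches closed forms", {
  expect_equal(exact_permutation_pvalue(c(1, 2, 3)), 2 / 8)
  expect_equal(exact_permutation_pvalue(rep(0.5, 7)), 2 / 128)
  expect_equal(exact_permutation_pvalue(rep(0.5, 7)), 0.015625)
  expect_equal(exact_permutation_pvalue(rep(1, 14)), 2 / 2^14)
  expect_equal(exact_permutation_pvalue(c(1, -1)), 1)   # T = 0
  expect_equal(exact_permutation_pvalue(c(0, 0, 0)), 1)
  expect_error(exact_permutation_pvalue(seq_len(25)), "enumeration")
})

test_that("permutation p equals the naive full-enumeration oracle", {
  set.seed(42)
  for (i in 1:100) {
    n <- sample(2:10, 1)
    # discrete values induce ties and zeros
    d <- sample(c(-3:-1, 0:3), n, replace = TRUE) +
      sample(c(0, 0, 0.5), n, replace = TRUE)
    for (zp in c("exclude", "pratt")) {
      expect_equal(exact_permutation_pvalue(d, zero_policy = zp),
                   naive_perm_p(d, zero_policy = zp),
                   tolerance = 1e-12,
                   info = paste("case", i, zp, paste(d, collapse = ",")))
    }
  }
})

test_that("BH adjustment reproduces the hand step-up and validates input", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.3), 0.3)
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
  # hand step-up oracle on a random vector
  set.seed(1)
  p <- runif(20)
  o <- order(p)
  m <- length(p)
  q_sorted <- rev(cummin(rev(p[o] * m / seq_len(m))))
  q_oracle <- numeric(m); q_oracle[o] <- pmin(1, q_sorted)
  expect_equal(bh_adjust(p), q_oracle, tolerance = 1e-12)
})

test_that("a constant one-log10 shift puts every shifted feature at the floor", {
  cfg <- sim_config(n_features = 200L, pi_de = 0.1, delta = 1,
                    delta_profile = rep(1, 7), noise_sd = 0.1,
                    dropout_a = 50)        # no dropout
  gp <- generate_proteome(cfg, seed = 2)
  pp <- run_proteome_pipeline(gp$matrix, pairing = "stage")
  res <- pp$de$results
  de_ids <- gp$truth$features$feature_id[gp$truth$features$is_de]
  expect_gt(length(de_ids), 0)
  # every shifted feature's differences share one sign, so its p sits
  # at the floor attainable for its nonzero-difference count (ties in
  # the quantile reference can zero out an occasional difference)
  idx <- res$feature_id %in% de_ids
  n_nz <- rowSums(pp$de$differences[res$feature_id[idx], , drop = FALSE] != 0)
  expect_true(all(res$p_value[idx] == 2 / 2^n_nz))
  expect_true(all(res$p_value[idx][n_nz == 7] == 0.015625))
})

test_that("BH calls are invariant to duplicating every feature", {
  gp <- generate_proteome(sim_config(n_features = 120L), seed = 9)
  pp <- run_proteome_pipeline(gp$matrix, pairing = "stage_replicate")
  x <- pp$expression
  dup <- expr_matrix(rbind(x$values,
                           `rownames<-`(x$values,
                                        paste0(rownames(x$values), "_b"))),
                     x$design, scale = x$scale, modality = x$modality,
                     detected = rbind(x$detected,
                                      `rownames<-`(x$detected,
                                                   paste0(rownames(x$detected),
                                                          "_b"))))
  de1 <- paired_de_test(x, pairing = "stage_replicate")
  de2 <- paired_de_test(dup, pairing = "stage_replicate")
  half <- seq_len(nrow(x$values))
  expect_equal(de2$results$p_value[half], de1$results$p_value)
  expect_equal(de2$results$q_value[half], de1$results$q_value)
})

test_that("features with too few complete pairs are flagged, not dropped", {
  m <- full_matrix(5, n_rep = 1)
  m$values[] <- rexp(length(m$values)) + 0.5
  des <- m$design
  # feature 2 detected only at a single stage in each treatment
  keep <- des$sample_id[des$stage == "oocyte"]
  m$values[2, !colnames(m$values) %in% keep] <- 0
  m <- expr_matrix(m$values, des, scale = "linear")
  lg <- log_transform(quantile_normalize(m), 10)
  de <- paired_de_test(lg, pairing = "stage")
  r <- de$results
  expect_equal(nrow(r), 5L)
  expect_true(r$insufficient_pairs[r$feature_id == "f02"])
  expect_equal(r$p_value[r$feature_id == "f02"], 1)
})

test_that("fold-change census: inclusive boundary, zero case, monotone", {
  m <- full_matrix(3, n_rep = 1)
  des <- m$design
  so <- des$sample_id[des$treatment == "superovulation"]
  nat <- des$sample_id[des$treatment == "natural"]
  m$values[1, ] <- 1
  m$values[1, so[des[match(so, des$sample_id), "stage"] == "8-cell"]] <- 4
  m <- expr_matrix(m$values, des, scale = "linear")
  cen <- fold_change_census(m)
  expect_equal(cen["8-cell", "fc_ge_4"], 1L)
  expect_equal(cen["8-cell", "fc_ge_5"], 0L)
  expect_equal(sum(cen[, "fc_ge_4"]), 1L)
  # identical treatment profiles: all zero
  ident <- full_matrix(5, n_rep = 1, fill = 2)
  expect_true(all(fold_change_census(ident) == 0L))
  # monotone in threshold on synthetic data
  gp <- generate_proteome(sim_config(n_features = 300L), seed = 4)
  pp <- run_proteome_pipeline(gp$matrix)
  expect_true(all(apply(pp$census, 1L, function(r) all(diff(r) <= 0))))
})

test_that("up/down classification is strict and direction-aware", {
  gp <- generate_proteome(sim_config(n_features = 400L), seed = 6)
  pp <- run_proteome_pipeline(gp$matrix, pairing = "stage_replicate")
  ud <- classify_up_down(pp$de, fc_cut = 2)
  r <- pp$de$results
  # strictness: exactly-2-fold features are not counted
  manual <- sum(r$significant & !is.na(r$max_abs_fc) & r$max_abs_fc > 2)
  expect_equal(unname(ud[["n_up"]] + ud[["n_down"]]) +
                 sum(r$significant & !is.na(r$max_abs_fc) &
                       r$max_abs_fc > 2 & r$direction == "none"),
               manual)
  # directions agree with the truth signs for recovered features
  tru <- gp$truth$features
  up_called <- r$feature_id[r$significant & r$direction == "up" &
                              r$max_abs_fc > 2]
  expect_true(mean(tru$sign[match(up_called, tru$feature_id)] == 1) > 0.9)
  # degenerate input
  empty <- pp$de
  empty$results <- empty$results[0, ]
  expect_equal(unname(classify_up_down(empty)), c(0L, 0L))
})

test_that("abundance shift check detects a shifted subset", {
  gp <- generate_proteome(sim_config(n_features = 550L, pi_de = 0),
                          seed = 8)
  rib <- compute_ribaq(gp$matrix)
  ids <- feature_ids(rib)
  base <- gp$truth$features$baseline
  top <- ids[order(-base)][1:50]          # high-abundance subset
  res <- abundance_shift_check(rib, top)
  expect_lt(res$p_value, 1e-6)
  expect_gt(res$shift, 0)
  # random subset is unremarkable
  set.seed(1)
  rnd <- sample(ids, 50)
  expect_gt(abundance_shift_check(rib, rnd)$p_value, 1e-4)
  expect_error(abundance_shift_check(rib, character(0)), "empty")
  expect_error(abundance_shift_check(rib, ids), "proper subset")
})
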