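test_that("riBAQ divides by per-sample detected totals", {
  m <- full_matrix(3)
  m$values[, 1] <- c(2, 3, 5)
  r <- compute_ribaq(m)
  expect_equal(unname(r$values[, 1]), c(0.2, 0.3, 0.5))
  # undetected cells stay undetected and are excluded from the total
  m2 <- full_matrix(3)
  m2$values[, 2] <- c(1, 0, 0)
  m2$detected[, 2] <- c(TRUE, FALSE, FALSE)
  m2 <- expr_matrix(m2$values, m2$design, scale = "linear",
                    detected = m2$detected)
  r2 <- compute_ribaq(m2)
  expect_equal(unname(r2$values[, 2]), c(1, 0, 0))
  expect_equal(unname(r2$detected[, 2]), c(TRUE, FALSE, FALSE))
  # conservation: every sample's detected riBAQ sums to 1
  gp <- generate_proteome(sim_config(n_features = 100L), seed = 3)
  rr <- compute_ribaq(gp$matrix)
  expect_equal(unname(colSums(rr$values)), rep(1, 28),
               tolerance = 1e-12)
  # all-zero sample is an error
  m3 <- full_matrix(2)
  m3$values[, 5] <- 0
  m3 <- expr_matrix(m3$values, m3$design, scale = "linear")
  expect_error(compute_ribaq(m3), "all-zero")
})

test_that("minimum-detection filter uses an inclusive boundary", {
  m <- full_matrix(3)                      # 28 samples
  m$values[1, -1] <- 0                     # detected in 1 sample
  m$values[2, -(1:2)] <- 0                 # detected in 2 samples
  m <- expr_matrix(m$values, m$design, scale = "linear")
  f <- filter_min_detection(m, 2L)
  expect_setequal(feature_ids(f$matrix), c("f02", "f03"))
  expect_equal(f$report$n_input_features, 3L)
  expect_equal(f$report$n_after_min_detection, 2L)
  expect_equal(feature_ids(filter_min_detection(m, 0L)$matrix),
               feature_ids(m))
})

test_that("constitutive filter requires every (stage, treatment) cell", {
  m <- full_matrix(3)
  des <- m$design
  drop_cols <- des$sample_id[des$stage == "morula" &
                             des$treatment == "natural"]
  m$values[2, drop_cols] <- 0              # both replicates of one cell
  m$values[3, drop_cols[1]] <- 0           # only one replicate
  m <- expr_matrix(m$values, m$design, scale = "linear")
  kept <- filter_constitutive(m)
  expect_setequal(feature_ids(kept), c("f01", "f03"))
  # idempotence
  expect_identical(filter_constitutive(kept)$values, kept$values)
  # empty matrix passes through
  empty <- subset_features(m, integer(0))
  expect_equal(nrow(filter_constitutive(empty)$values), 0L)
  # missing design cell is an error
  sub <- subset_features(m, samples = which(!(des$stage == "morula" &
                                              des$treatment == "natural")))
  expect_error(filter_constitutive(sub), "morula, natural")
})

test_that("replicate averaging follows the detected-value rule", {
  m <- full_matrix(1)
  des <- m$design
  cell <- des$sample_id[des$stage == "oocyte" &
                        des$treatment == "superovulation"]
  m$values[1, cell] <- c(0.2, 0.4)
  cell2 <- des$sample_id[des$stage == "1-cell" &
                         des$treatment == "superovulation"]
  m$values[1, cell2] <- c(0.2, 0)
  cell3 <- des$sample_id[des$stage == "2-cell" &
                         des$treatment == "superovulation"]
  m$values[1, cell3] <- 0
  m <- expr_matrix(m$values, m$design, scale = "linear")
  a <- average_replicates(m)
  expect_equal(a$values[1, "oocyte.superovulation"], 0.3)
  expect_equal(a$values[1, "1-cell.superovulation"], 0.2)
  expect_false(a$detected[1, "2-cell.superovulation"])
  expect_equal(ncol(a$values), 14L)
})

test_that("quantile normalization: two-column example, identity, means", {
  des <- sample_design(c("A", "B"), c("oocyte", "oocyte"),
                       c("superovulation", "natural"), c(1L, 1L))
  v <- matrix(c(1, 2, 3, 4, 5, 6), 3, 2,
              dimnames = list(c("f1", "f2", "f3"), c("A", "B")))
  m <- expr_matrix(v, des, scale = "linear")
  q <- quantile_normalize(m)
  expect_equal(unname(q$values), matrix(c(2.5, 3.5, 4.5), 3, 2,
                                        byrow = FALSE) + c(0, 0, 0),
               tolerance = 1e-12)
  # identical columns are unchanged; idempotence
  v2 <- matrix(c(3, 1, 7, 3, 1, 7), 3, 2,
               dimnames = dimnames(v))
  m2 <- expr_matrix(v2, des, scale = "linear")
  expect_equal(quantile_normalize(m2)$values, m2$values)
  q2 <- quantile_normalize(q)
  expect_equal(q2$values, q$values, tolerance = 1e-12)
  expect_equal(mean(q$values[, 1]), mean(q$values[, 2]))
})

test_that("log transform is exact and errors on non-positive values", {
  des <- sample_design("A", "oocyte", "natural", 1L)
  m <- expr_matrix(matrix(c(100, 1), 2, 1,
                          dimnames = list(c("f1", "f2"), "A")),
                   des, scale = "linear")
  lg <- log_transform(m, 10)
  expect_equal(unname(lg$values[, 1]), c(2, 0))
  expect_equal(lg$scale, "log10")
  expect_equal(10^lg$values, m$values, tolerance = 1e-12)
  expect_error(log_transform(lg, 10), "log scale")
  expect_error(log_transform(m, 7), "base")
})

test_that("median-of-ratios size factors match the hand-computed toy", {
  des <- sample_design(c("A", "B"), c("oocyte", "oocyte"),
                       c("superovulation", "natural"), c(1L, 1L))
  v <- matrix(c(2, 8, 32, 4, 16, 64), 3, 2,
              dimnames = list(paste0("g", 1:3), c("A", "B")))
  m <- expr_matrix(v, des, scale = "linear", modality = "transcript")
  nc <- normalize_counts(m)
  expect_equal(unname(nc$report$size_factors),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_equal(nc$matrix$scale, "log2")
  expect_equal(unname(nc$matrix$values[1, ]),
               log2(c(2 / (1 / sqrt(2)), 4 / sqrt(2)) + 1))
  # identical samples give unit factors
  v2 <- v; v2[, 2] <- v[, 1]
  nc2 <- normalize_counts(expr_matrix(v2, des, scale = "linear",
                                      modality = "transcript"))
  expect_equal(unname(nc2$report$size_factors), c(1, 1))
  # equivariance: scaling one sample scales its factor
  v3 <- v; v3[, 2] <- v[, 2] * 3
  nc3 <- normalize_counts(expr_matrix(v3, des, scale = "linear",
                                      modality = "transcript"))
  expect_equal(unname(nc3$report$size_factors[2] /
                        nc$report$size_factors[2]),
               unname(3 * (nc3$report$size_factors[1] /
                             nc$report$size_factors[1])),
               tolerance = 1e-12)
  # no all-positive feature is an error
  v4 <- v; v4[, 1] <- 0
  m4 <- expr_matrix(v4, des, scale = "linear", modality = "transcript")
  expect_error(normalize_counts(m4), "pseudocount")
})

test_that("size factors agree with the standard median-of-ratios tool", {
  gt <- generate_transcriptome(sim_config(t_n_features = 300L), seed = 5)
  counts <- gt$matrix$values
  keep <- rowSums(counts > 0) == ncol(counts)
  nc <- normalize_counts(gt$matrix)
  ref <- DESeq2::estimateSizeFactorsForMatrix(counts)
  expect_equal(unname(nc$report$size_factors), unname(ref),
               tolerance = 1e-8)
})
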