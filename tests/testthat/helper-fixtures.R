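# shared fixture builders; everything is constructed in code

# full 7-stage x 2-treatment x n_rep design
full_design <- function(n_rep = 2L) {
  g <- expand.grid(replicate = seq_len(n_rep),
                   treatment = treatment_levels(),
                   stage = stage_levels(),
                   stringsAsFactors = FALSE)
  sample_design(
    sample_id = paste0("s", seq_len(nrow(g))),
    stage = g$stage, treatment = g$treatment, replicate = g$replicate
  )
}

# linear expr_matrix with a full design; values recycled row-wise
full_matrix <- function(n_features = 3L, n_rep = 2L, fill = 1,
                        modality = "protein") {
  des <- full_design(n_rep)
  v <- matrix(fill, n_features, nrow(des),
              dimnames = list(sprintf("f%02d", seq_len(n_features)),
                              des$sample_id))
  expr_matrix(v, des, scale = "linear", modality = modality)
}

# independent oracle: exact sign-flip p by enumerating every sign
# vector and recomputing the statistic, no rank caching
naive_perm_p <- function(d, zero_policy = "exclude") {
  d <- d[!is.na(d)]
  if (zero_policy == "exclude") {
    dd <- d[d != 0]
    if (!length(dd)) return(1)
    r <- rank(abs(dd))
    s0 <- sign(dd)
  } else {
    r_all <- rank(abs(d))
    keep <- d != 0
    if (!any(keep)) return(1)
    r <- r_all[keep]
    s0 <- sign(d)[keep]
  }
  t_obs <- abs(sum(s0 * r))
  signs <- as.matrix(expand.grid(rep(list(c(-1, 1)), length(r))))
  t_all <- abs(as.vector(signs %*% r))
  mean(t_all >= t_obs - 1e-9)
}

# independent oracle: naive complete-linkage agglomeration returning
# the cophenetic distance matrix
naive_complete_cophenetic <- function(D) {
  D <- as.matrix(D)
  n <- nrow(D)
  labs <- rownames(D)
  clusters <- as.list(seq_len(n))
  coph <- matrix(0, n, n, dimnames = list(labs, labs))
  cd <- function(a, b) max(D[clusters[[a]], clusters[[b]]])
  while (length(clusters) > 1L) {
    m <- length(clusters)
    best <- c(Inf, NA, NA)
    for (a in seq_len(m - 1L)) for (b in (a + 1L):m) {
      d <- cd(a, b)
      if (d < best[1L]) best <- c(d, a, b)
    }
    a <- best[2L]; b <- best[3L]
    coph[clusters[[a]], clusters[[b]]] <- best[1L]
    coph[clusters[[b]], clusters[[a]]] <- best[1L]
    clusters[[a]] <- c(clusters[[a]], clusters[[b]])
    clusters[[b]] <- NULL
  }
  coph
}

# independent oracle: hypergeometric upper tail by brute-force
# enumeration of all possible queries of size n from a universe of
# size N (N <= 12)
brute_force_hyper_p <- function(N, K, n, k_obs) {
  universe <- seq_len(N)
  term <- seq_len(K)
  qs <- utils::combn(N, n)
  k <- apply(qs, 2L, function(q) length(intersect(q, term)))
  mean(k >= k_obs)
}

# independent oracle: two-sided Fisher p by probability-mass sweep
# over the conditional hypergeometric support with fixed margins
fisher_sweep_p <- function(tab) {
  r1 <- sum(tab[1, ]); c1 <- sum(tab[, 1]); N <- sum(tab)
  lo <- max(0L, r1 + c1 - N); hi <- min(r1, c1)
  support <- lo:hi
  pr <- stats::dhyper(support, c1, N - c1, r1)
  p_obs <- stats::dhyper(tab[1, 1], c1, N - c1, r1)
  sum(pr[pr <= p_obs * (1 + 1e-7)])
}
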