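## internal: case-insensitive, whitespace-stripped id canonicalization
.canon_ids <- function(ids) toupper(trimws(as.character(ids)))

#' Hypergeometric over-representation of one term
#'
#' Exact upper-tail probability `P(X >= k)` for the overlap `k` between
#' a query of size `n` and a term of size `K` inside a universe of size
#' `N`, under Hypergeometric(N, K, n).
#'
#' @param query character vector of query feature ids (must lie in the
#'   universe).
#' @param term character vector of term member ids (intersected with
#'   the universe).
#' @param universe character vector of background feature ids.
#' @return List with `k` (overlap), `K` (term size in universe), `n`
#'   (query size), `N` (universe size), `p` (upper-tail probability).
#' @export
hypergeometric_enrichment <- function(query, term, universe) {
  universe <- unique(.canon_ids(universe))
  query <- unique(.canon_ids(query))
  term <- unique(.canon_ids(term))
  if (!length(universe)) stop("empty universe")
  if (!length(query)) stop("empty query")
  outside <- setdiff(query, universe)
  if (length(outside))
    stop("query id(s) outside the universe: ",
         paste(utils::head(outside, 3), collapse = ", "))
  term <- intersect(term, universe)
  N <- length(universe)
  K <- length(term)
  n <- length(query)
  k <- length(intersect(query, term))
  p <- if (k == 0L) 1
       else stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE)
  list(k = k, K = K, n = n, N = N, p = min(1, p))
}

#' Monte-Carlo z-score of the rank deviation of a term
#'
#' Draws `n_resamples` random queries of the observed query size from
#' the universe, ranks all terms of the collection by hypergeometric
#' p-value in every draw, and returns
#' `z = (mean_rank - observed_rank) / sd_rank` for the requested term
#' (positive = the term ranks better than expected under random
#' queries). Seeded and reproducible.
#'
#' @param term_id id of the term of interest within `collection`.
#' @param collection a `gene_set_collection` (see [read_gmt()]).
#' @param query_size integer size of the observed query.
#' @param universe background feature ids.
#' @param observed_rank the term's observed p-value rank within the
#'   collection (mid-ranks for ties), as computed by [enrich()].
#' @param n_resamples number of random queries (>= 100; default 1000).
#' @param seed integer seed.
#' @return The z-score (0, with a warning, when the resampled rank is
#'   degenerate).
#' @export
rank_deviation_z <- function(term_id, collection, query_size, universe,
                             observed_rank,
                             n_resamples = 1000L, seed = 1L) {
  if (n_resamples < 100L) stop("n_resamples must be >= 100")
  if (!term_id %in% names(collection))
    stop("term '", term_id, "' not in collection")
  obs <- rep(NA_real_, length(collection))
  obs[match(term_id, names(collection))] <- observed_rank
  z <- .rank_deviation_z_all(collection, query_size, universe,
                             n_resamples, seed, observed_ranks = obs)
  z[match(term_id, names(collection))]
}

## internal: z for every term given the observed rank vector.
## Resampled ranks are computed once for the whole collection.
.rank_deviation_z_all <- function(collection, query_size, universe,
                                  n_resamples, seed, observed_ranks) {
  universe <- unique(.canon_ids(universe))
  sets <- lapply(collection, function(m)
    intersect(unique(.canon_ids(m)), universe))
  N <- length(universe)
  K <- lengths(sets)
  nt <- length(sets)
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old))
    assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed)
  memb <- matrix(FALSE, N, nt)          # universe x terms membership
  for (j in seq_len(nt)) memb[match(sets[[j]], universe), j] <- TRUE
  ranks <- matrix(NA_real_, n_resamples, nt)
  for (b in seq_len(n_resamples)) {
    idx <- sample.int(N, query_size)
    k <- colSums(memb[idx, , drop = FALSE])
    p <- ifelse(k == 0, 1,
                stats::phyper(k - 1, K, N - K, query_size,
                              lower.tail = FALSE))
    ranks[b, ] <- rank(p, ties.method = "average")
  }
  mu <- colMeans(ranks)
  sdv <- apply(ranks, 2L, stats::sd)
  z <- (mu - observed_ranks) / sdv
  degen <- sdv == 0 & !is.na(observed_ranks)
  if (any(degen)) {
    warning("degenerate resampled rank distribution for ",
            sum(degen), " term(s); z set to 0")
    z[degen] <- 0
  }
  z
}

#' Gene-set over-representation analysis
#'
#' Per-term hypergeometric p-values, Benjamini-Hochberg q-values across
#' the collection, a Monte-Carlo rank-deviation z-score, and an
#' Enrichr-style combined score. The combined score is
#' `-ln(p) * z`, i.e. the log p-value multiplied by the rank-deviation
#' z with the sign arranged so that enriched terms (small p, better-
#' than-expected rank) receive positive scores. The output keeps terms
#' with `q <= fdr_cut`, then the `top` smallest-p terms, sorted by
#' combined score, descending.
#'
#' Identifiers are matched case-insensitively after whitespace
#' stripping; query ids absent from the universe raise an error rather
#' than being dropped silently.
#'
#' @param query character vector of feature ids.
#' @param collection a `gene_set_collection` ([read_gmt()]) or named
#'   list of member-id vectors.
#' @param universe background ids; defaults to the analyzed feature set
#'   and should normally be the constitutive set, not the whole genome.
#' @param fdr_cut FDR threshold for calling a term enriched (default
#'   0.01).
#' @param top number of reported terms (default 10; `0` returns an
#'   empty table).
#' @param n_resamples,seed Monte-Carlo settings for the z-score.
#' @return A data.frame of class `enrichment_result` with columns
#'   `term_id`, `k`, `K`, `n`, `N`, `p_hyper`, `q_bh`, `z_rank`,
#'   `combined_score`.
#' @export
enrich <- function(query, collection, universe,
                   fdr_cut = 0.01, top = 10L,
                   n_resamples = 1000L, seed = 1L) {
  if (!length(collection)) stop("empty gene-set collection")
  terms <- names(collection)
  hg <- lapply(collection, function(m)
    hypergeometric_enrichment(query, m, universe))
  p <- vapply(hg, `[[`, 0, "p")
  q <- bh_adjust(p)
  obs_rank <- rank(p, ties.method = "average")
  z <- .rank_deviation_z_all(collection,
                             query_size = hg[[1L]]$n,
                             universe = universe,
                             n_resamples = n_resamples, seed = seed,
                             observed_ranks = obs_rank)
  res <- data.frame(
    term_id = terms,
    k = vapply(hg, `[[`, 0L, "k"),
    K = vapply(hg, `[[`, 0L, "K"),
    n = vapply(hg, `[[`, 0L, "n"),
    N = vapply(hg, `[[`, 0L, "N"),
    p_hyper = p,
    q_bh = q,
    z_rank = z,
    combined_score = -log(p) * z,
    stringsAsFactors = FALSE,
    row.names = NULL
  )
  res <- res[res$q_bh <= fdr_cut, , drop = FALSE]
  res <- res[order(res$p_hyper), , drop = FALSE]
  res <- utils::head(res, max(0L, top))
  res <- res[order(-res$combined_score), , drop = FALSE]
  rownames(res) <- NULL
  class(res) <- c("enrichment_result", "data.frame")
  res
}
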