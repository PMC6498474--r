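#' Over-representation testing of a query gene list
#'
#' Tests whether the overlap between a query list and each gene set of a
#' collection is larger than expected by chance, using the upper-tail
#' hypergeometric probability `P(X >= k)` with population size `N` (the
#' universe), `K` successes (the set after intersection with the universe)
#' and `n` draws (the query). The universe must be supplied explicitly —
#' typically all genes tested in the differential-expression stage — because
#' silently inferring it is the classic enrichment pitfall. P values are
#' BH-adjusted across all tested sets.
#'
#' The combined score follows the published rank-deviation construction:
#' `-ln(p) * z`, where `z` is the standardized deviation of the set's
#' observed rank (by p value) from its expected rank under `n_random` seeded
#' random queries of the same size, so that sets which rank better than their
#' chance behaviour score higher.
#'
#' @param query Character vector of query gene symbols. Genes outside the
#'   universe are dropped with a warning.
#' @param collection A [gene_set_collection()].
#' @param universe Character vector of background gene symbols.
#' @param min_set_size Sets smaller than this after universe intersection are
#'   skipped.
#' @param ignore_case Match gene symbols case-insensitively (for collections
#'   mixing human upper-case and mouse mixed-case symbols). Default exact.
#' @param n_random Number of random queries used to calibrate the combined
#'   score (0 disables the combined score).
#' @param seed Integer seed for the random queries.
#' @return A data frame sorted by adjusted p, one row per tested set:
#'   `set`, `overlap` (k), `set_size` (K), `query_size` (n),
#'   `universe_size` (N), `P.Value`, `adj.P.Val`, `odds_ratio`,
#'   `combined_score`, `genes` (comma-separated overlap).
#' @export
hypergeometric_enrich <- function(query, collection, universe,
                                  min_set_size = 1, ignore_case = FALSE,
                                  n_random = 100, seed = 1) {
  stopifnot(inherits(collection, "gene_set_collection"))
  norm <- if (ignore_case) toupper else identity
  universe <- unique(norm(as.character(universe)))
  query <- unique(norm(as.character(query)))
  if (!length(universe)) stopf("'universe' must not be empty")
  if (!length(query)) stopf("'query' must not be empty")
  outside <- setdiff(query, universe)
  if (length(outside)) {
    warnf("%d query gene(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  if (!length(query)) stopf("no query genes remain within the universe")

  sets <- lapply(collection, function(s) intersect(norm(s$genes), universe))
  names(sets) <- vapply(collection, function(s) s$name, character(1))
  sets <- sets[lengths(sets) >= min_set_size]
  if (!length(sets)) stopf("no gene set meets 'min_set_size' after universe intersection")

  N <- length(universe)
  n <- length(query)
  K <- lengths(sets)
  overlap_genes <- lapply(sets, intersect, query)
  k <- lengths(overlap_genes)
  p <- stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
  odds <- (k * (N - K - n + k)) / pmax(n - k, 0) / pmax(K - k, 0)

  z <- rep(NA_real_, length(sets))
  if (n_random > 0) {
    null_ranks <- with_seed(seed, {
      vapply(seq_len(n_random), function(b) {
        rq <- sample(universe, n)
        kb <- vapply(sets, function(s) length(intersect(s, rq)), integer(1))
        pb <- stats::phyper(kb - 1, K, N - K, n, lower.tail = FALSE)
        rank(pb, ties.method = "average")
      }, numeric(length(sets)))
    })
    mu <- rowMeans(null_ranks)
    sd0 <- apply(null_ranks, 1, stats::sd)
    obs_rank <- rank(p, ties.method = "average")
    z <- ifelse(sd0 > 0, (mu - obs_rank) / sd0, 0)
  }

  res <- data.frame(set = names(sets), overlap = k, set_size = K,
                    query_size = n, universe_size = N, P.Value = p,
                    adj.P.Val = bh_adjust(p), odds_ratio = odds,
                    combined_score = -log(pmax(p, .Machine$double.xmin)) * z,
                    genes = vapply(overlap_genes, paste, character(1),
                                   collapse = ","),
                    row.names = NULL, stringsAsFactors = FALSE)
  res[order(res$adj.P.Val, res$P.Value, res$set), , drop = FALSE]
}

#' Construct a ranked gene profile
#'
#' A ranked profile is a named numeric vector of finite scores, one per
#' unique gene, ordered descending — the form a differential-expression
#' ranking takes (e.g. moderated t or signed significance).
#'
#' @param scores Named numeric vector (names are gene symbols). Sorted
#'   descending if not already.
#' @return A named numeric vector of class `ranked_profile`.
#' @export
ranked_profile <- function(scores) {
  if (!is.numeric(scores) || is.null(names(scores)) ||
      any(!nzchar(names(scores)))) {
    stopf("'scores' must be a named numeric vector")
  }
  if (any(!is.finite(scores))) stopf("profile scores must be finite")
  if (anyDuplicated(names(scores))) {
    stopf("duplicate gene(s) in profile: %s",
          paste(unique(names(scores)[duplicated(names(scores))]),
                collapse = ", "))
  }
  scores <- sort(scores, decreasing = TRUE)
  structure(scores, class = "ranked_profile")
}

#' Weighted running-sum enrichment score
#'
#' Walks down the ranked list accumulating a hit-minus-miss sum: a gene in
#' the set contributes `|score|^weight` normalized by the sum of
#' `|score|^weight` over the set members present in the profile, a gene
#' outside the set contributes `-1/(N - m)` where `m` is the number of set
#' members in the profile. The enrichment score is the signed maximum
#' deviation of the running sum from zero. With `weight = 0` this is the
#' classic Kolmogorov-Smirnov statistic comparing the set's positions to
#' uniform, and is invariant under monotone rescaling of the scores.
#'
#' @param profile A [ranked_profile()] (or a named numeric vector, which is
#'   sorted descending).
#' @param gene_set A [gene_set()] or character vector of member genes; its
#'   intersection with the profile must be non-empty.
#' @param weight Non-negative hit-weighting exponent (default 1).
#' @param detailed If `TRUE`, also return the running sum and the position
#'   of the extreme.
#' @return The enrichment score (scalar), or a list with `es`, `running`,
#'   `position` when `detailed = TRUE`.
#' @export
gsea_running_sum <- function(profile, gene_set, weight = 1,
                             detailed = FALSE) {
  if (!inherits(profile, "ranked_profile")) profile <- ranked_profile(profile)
  genes <- if (inherits(gene_set, "gene_set")) gene_set$genes else
    as.character(gene_set)
  if (!is_scalar_number(weight) || weight < 0) {
    stopf("'weight' must be a non-negative number")
  }
  hit <- names(profile) %in% genes
  m <- sum(hit)
  if (m == 0L) stopf("gene set is disjoint from the profile")
  es_from_hits(as.numeric(profile), which(hit), weight, detailed)
}

# Core running-sum computation given hit positions in a descending profile.
es_from_hits <- function(scores, hit_pos, weight, detailed = FALSE) {
  N <- length(scores)
  m <- length(hit_pos)
  hit_pos <- sort(hit_pos)
  w <- abs(scores[hit_pos])^weight
  total <- sum(w)
  if (total == 0) w[] <- 1 / m else w <- w / total
  miss_inc <- if (N > m) 1 / (N - m) else 0
  # running sum evaluated at its candidate extremes: just after each hit
  # (local maxima) and just before each hit (local minima)
  cum_hit <- cumsum(w)
  at_hit <- cum_hit - (hit_pos - seq_len(m)) * miss_inc
  before_hit <- c(0, cum_hit[-m]) - (hit_pos - seq_len(m)) * miss_inc
  extremes <- c(at_hit, before_hit)
  idx <- which.max(abs(extremes))
  es <- extremes[idx]
  if (!detailed) return(es)
  running <- numeric(N)
  inc <- rep(-miss_inc, N)
  inc[hit_pos] <- w
  running <- cumsum(inc)
  list(es = es, running = running,
       position = if (idx <= m) hit_pos[idx] else hit_pos[idx - m] - 1L)
}

#' Permutation significance for running-sum enrichment
#'
#' For each gene set, the observed enrichment score is compared to a null
#' distribution obtained by gene-label permutation: the set's labels are
#' reassigned to random positions of the profile `n_perm` times. The p value
#' is the fraction of same-sign null scores at least as extreme as the
#' observed one (with a +1 continuity correction so p is never 0); the
#' normalized enrichment score (NES) divides the observed score by the mean
#' magnitude of same-sign null scores; and the FDR uses the ratio-of-tails
#' convention over the pooled normalized null. Deterministic given `seed`.
#'
#' @param profile A [ranked_profile()] (or named numeric vector).
#' @param collection A [gene_set_collection()].
#' @param n_perm Number of permutations (at least 100).
#' @param seed Integer seed.
#' @param weight Hit-weighting exponent passed to [gsea_running_sum()].
#' @param min_size Minimum set size (after intersection with the profile).
#' @return A data frame with one row per tested set: `set`, `size`, `ES`,
#'   `NES`, `P.Value`, `FDR`.
#' @export
gsea_significance <- function(profile, collection, n_perm = 1000, seed = 1,
                              weight = 1, min_size = 1) {
  if (!inherits(profile, "ranked_profile")) profile <- ranked_profile(profile)
  stopifnot(inherits(collection, "gene_set_collection"))
  if (!is_count(n_perm) || n_perm < 100) {
    stopf("'n_perm' must be an integer >= 100")
  }
  scores <- as.numeric(profile)
  N <- length(scores)
  sizes <- vapply(collection, function(s) {
    sum(names(profile) %in% s$genes)
  }, integer(1))
  keep <- sizes >= min_size & sizes >= 1 & sizes < N
  if (!any(keep)) stopf("no gene set overlaps the profile at 'min_size'")
  tested <- collection[keep]
  sizes <- sizes[keep]

  with_seed(seed, {
    res <- vector("list", length(tested))
    pooled_null <- list()
    for (i in seq_along(tested)) {
      hit_pos <- which(names(profile) %in% tested[[i]]$genes)
      es <- es_from_hits(scores, hit_pos, weight)
      null_es <- vapply(seq_len(n_perm), function(b) {
        es_from_hits(scores, sample.int(N, sizes[i]), weight)
      }, numeric(1))
      same <- null_es * sign(es) > 0
      n_same <- sum(same)
      p <- (1 + sum(abs(null_es[same]) >= abs(es))) / (1 + n_same)
      denom <- if (n_same > 0) mean(abs(null_es[same])) else NA_real_
      nes <- if (is.na(denom) || denom == 0) NA_real_ else es / denom
      # normalize the null by the same sign-wise means for the pooled FDR
      pos_mean <- mean(abs(null_es[null_es > 0]))
      neg_mean <- mean(abs(null_es[null_es < 0]))
      null_nes <- ifelse(null_es > 0, null_es / pos_mean,
                         null_es / neg_mean)
      pooled_null[[i]] <- null_nes[is.finite(null_nes)]
      res[[i]] <- data.frame(set = tested[[i]]$name, size = sizes[i],
                             ES = es, NES = nes, P.Value = p,
                             stringsAsFactors = FALSE)
    }
    out <- do.call(rbind, res)
    pooled <- unlist(pooled_null)
    out$FDR <- vapply(seq_len(nrow(out)), function(i) {
      nes <- out$NES[i]
      if (is.na(nes)) return(NA_real_)
      sgn <- sign(nes)
      null_tail <- mean(pooled * sgn > 0 & abs(pooled) >= abs(nes))
      null_side <- mean(pooled * sgn > 0)
      obs_tail <- mean(out$NES * sgn > 0 & abs(out$NES) >= abs(nes),
                       na.rm = TRUE)
      if (null_side == 0 || obs_tail == 0) return(1)
      min(1, (null_tail / null_side) / obs_tail)
    }, numeric(1))
    rownames(out) <- NULL
    out[order(out$P.Value, out$set), , drop = FALSE]
  })
}
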