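# Independent brute-force oracles used to validate the package's
# implementations, deliberately written with none of the package's code
# paths.

# Benjamini-Hochberg by the literal min-over-suffix definition.
brute_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  adj_sorted <- numeric(m)
  for (i in seq_len(m)) {
    adj_sorted[i] <- min(1, min(sorted[i:m] * m / (i:m)))
  }
  adj <- numeric(m)
  adj[ord] <- adj_sorted
  adj
}

# Upper-tail hypergeometric probability by exhaustive enumeration of all
# C(N, n) draws (feasible for N <= 12).
brute_hyper_tail <- function(N, K, n, k) {
  draws <- utils::combn(N, n)
  hits <- colSums(draws <= K)  # successes are items 1..K
  mean(hits >= k)
}

# Literal walk of the weighted running sum: one step per profile position.
brute_es <- function(scores, hit, weight) {
  N <- length(scores)
  m <- sum(hit)
  w <- abs(scores[hit])^weight
  w <- if (sum(w) == 0) rep(1 / m, m) else w / sum(w)
  hit_inc <- numeric(N)
  hit_inc[hit] <- w
  running <- 0
  best <- 0
  j <- 0
  for (i in seq_len(N)) {
    running <- running + if (hit[i]) hit_inc[i] else -1 / (N - m)
    if (abs(running) > abs(best)) best <- running
  }
  best
}

# Per-gene counting oracle for consensus membership.
brute_consensus <- function(studies, tag, thresholds = c(0.3, 0.5, 0.7)) {
  k <- sum(vapply(studies, function(s) {
    !is.null(s$up) || !is.null(s$down)
  }, logical(1)))
  all_genes <- unique(unlist(lapply(studies, function(s) {
    c(if (!is.null(s$up)) s$up$genes, if (!is.null(s$down)) s$down$genes)
  })))
  out <- list()
  for (tau in thresholds) {
    for (cat in c("up", "down", "same")) {
      members <- character()
      for (g in all_genes) {
        U <- sum(vapply(studies, function(s) {
          !is.null(s$up) && g %in% s$up$genes
        }, logical(1)))
        D <- sum(vapply(studies, function(s) {
          !is.null(s$down) && g %in% s$down$genes
        }, logical(1)))
        keep <- switch(cat,
          up = U / k >= tau - 1e-12 && D == 0,
          down = D / k >= tau - 1e-12 && U == 0,
          same = (U + D) / k >= tau - 1e-12 && min(U, D) == 0)
        if (keep) members <- c(members, g)
      }
      out[[paste0(tag, "__", cat, round(tau * 100))]] <- sort(members)
    }
  }
  out
}

# Random gene-set collections for round-trip property tests.
random_collection <- function(n_sets, pool = sprintf("GENE%03d", 1:60),
                              p_empty = 0.2) {
  sets <- lapply(seq_len(n_sets), function(i) {
    n_genes <- if (stats::runif(1) < p_empty) 0 else sample(1:15, 1)
    gene_set(sprintf("set_%03d", i), sprintf("SRC%d", i),
             sample(pool, n_genes))
  })
  gene_set_collection(sets)
}

# A pair of up/down gene_set objects for one synthetic study.
study_pair <- function(up_genes, down_genes, id) {
  meta <- comparison_meta("trt", "ctl", "mouse", "musc", sprintf("S%d", id),
                          id)
  list(up = gene_set(build_set_name(meta, "up"), meta$source_id, up_genes),
       down = gene_set(build_set_name(meta, "down"), meta$source_id,
                       down_genes))
}
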