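tiny_universe <- sprintf("G%02d", 1:10)

collection_of <- function(...) {
  sets <- list(...)
  gene_set_collection(lapply(seq_along(sets), function(i) {
    gene_set(paste0("set", i), "src", sets[[i]])
  }))
}

test_that("the hypergeometric tail matches the hand-enumerated example", {
  # N=10, K=3, n=3, k=2 -> P = [C(3,2)C(7,1) + C(3,3)C(7,0)] / C(10,3)
  col <- collection_of(tiny_universe[1:3])
  res <- hypergeometric_enrich(c(tiny_universe[1:2], tiny_universe[10]),
                               col, tiny_universe, n_random = 0)
  expect_equal(res$overlap, 2L)
  expect_equal(res$P.Value, 22 / 120, tolerance = 1e-12)
})

test_that("zero overlap gives p = 1 and a full query gives k = K", {
  col <- collection_of(tiny_universe[1:3], tiny_universe[4:8])
  res0 <- hypergeometric_enrich(tiny_universe[9:10], col, tiny_universe,
                                n_random = 0)
  expect_true(all(res0$P.Value == 1))
  resall <- hypergeometric_enrich(tiny_universe, col, tiny_universe,
                                  n_random = 0)
  expect_equal(resall$overlap, resall$set_size)
  expect_true(all(resall$P.Value == 1))
})

test_that("tail probabilities agree with exhaustive enumeration for N <= 12", {
  set.seed(1)
  for (rep in 1:12) {
    N <- sample(5:12, 1)
    uni <- sprintf("U%02d", 1:N)
    K <- sample(1:(N - 1), 1)
    n <- sample(1:(N - 1), 1)
    query <- sample(uni, n)
    col <- collection_of(sample(uni, K))
    res <- hypergeometric_enrich(query, col, uni, n_random = 0)
    expect_equal(res$P.Value, brute_hyper_tail(N, K, n, res$overlap),
                 tolerance = 1e-10)
  }
})

test_that("over-representation is invariant to query order and warns on outside genes", {
  col <- collection_of(tiny_universe[1:4])
  a <- hypergeometric_enrich(tiny_universe[c(2, 4, 7)], col, tiny_universe,
                             n_random = 0)
  b <- hypergeometric_enrich(tiny_universe[c(7, 2, 4)], col, tiny_universe,
                             n_random = 0)
  expect_equal(a$P.Value, b$P.Value)
  expect_warning(
    hypergeometric_enrich(c("NOTAGENE", tiny_universe[1:2]), col,
                          tiny_universe, n_random = 0),
    "outside the universe")
  expect_error(hypergeometric_enrich(character(), col, tiny_universe),
               "query")
  expect_error(hypergeometric_enrich("A", col, character()), "universe")
})

test_that("case-insensitive matching unifies human and mouse symbol styles", {
  col <- collection_of(c("Myod1", "Des"))
  res <- hypergeometric_enrich("MYOD1", col, c("MYOD1", "DES", "TTN", "ACTB"),
                               ignore_case = TRUE, n_random = 0)
  expect_equal(res$overlap, 1L)
  expect_error(
    hypergeometric_enrich("MYOD1", col, c("MYOD1", "DES", "TTN", "ACTB"),
                          ignore_case = FALSE, n_random = 0),
    "min_set_size")
})

test_that("the combined score rewards sets ranking better than chance", {
  set.seed(2)
  uni <- sprintf("U%03d", 1:200)
  enriched <- uni[1:20]
  col <- collection_of(enriched, sample(uni, 20), sample(uni, 20))
  query <- c(enriched[1:15], sample(setdiff(uni, enriched), 10))
  res <- hypergeometric_enrich(query, col, uni, n_random = 50, seed = 9)
  expect_equal(res$set[1], "set1")
  expect_gt(res$combined_score[1], max(res$combined_score[-1]))
})

test_that("the running sum matches its hand-walked value on a 4-gene profile", {
  prof <- c(a = 4, b = 3, c = 2, d = 1)
  # hits at ranks 1 and 3; weights 4/6 and 2/6; misses subtract 1/2:
  # walk: 2/3, 1/6, 1/2, 0 -> ES = 2/3 at rank 1
  es <- gsea_running_sum(prof, c("a", "c"))
  expect_equal(es, 2 / 3, tolerance = 1e-12)
  det <- gsea_running_sum(prof, c("a", "c"), detailed = TRUE)
  expect_equal(det$running, c(2 / 3, 1 / 6, 1 / 2, 0), tolerance = 1e-12)
  expect_equal(det$position, 1L)
  # a set holding only the top-ranked gene scores 1
  expect_equal(gsea_running_sum(prof, "a"), 1)
  expect_error(gsea_running_sum(prof, c("x", "y")), "disjoint")
})

test_that("the running sum agrees with the literal walk oracle", {
  set.seed(3)
  for (rep in 1:25) {
    N <- sample(5:60, 1)
    scores <- sort(rnorm(N, 0, 2), decreasing = TRUE)
    names(scores) <- sprintf("g%03d", 1:N)
    m <- sample(1:(N - 1), 1)
    hit <- rep(FALSE, N)
    hit[sample(N, m)] <- TRUE
    w <- sample(c(0, 0.5, 1, 2), 1)
    expect_equal(gsea_running_sum(scores, names(scores)[hit], weight = w),
                 brute_es(scores, hit, w), tolerance = 1e-12)
  }
})

test_that("at weight zero the score ignores monotone rescaling", {
  set.seed(4)
  scores <- sort(rexp(30), decreasing = TRUE)
  names(scores) <- paste0("g", 1:30)
  set_genes <- names(scores)[c(2, 5, 11, 20)]
  es0 <- gsea_running_sum(scores, set_genes, weight = 0)
  rescaled <- scores^3 + 1
  expect_equal(gsea_running_sum(rescaled, set_genes, weight = 0), es0)
})

test_that("fgsea computes the same enrichment statistic", {
  skip_if_not_installed("fgsea")
  set.seed(5)
  scores <- sort(rnorm(50), decreasing = TRUE)
  names(scores) <- paste0("g", 1:50)
  idx <- sort(sample(50, 8))
  ours <- gsea_running_sum(scores, names(scores)[idx], weight = 1)
  ref <- fgsea::calcGseaStat(scores, selectedStats = idx, gseaParam = 1)
  expect_equal(ours, ref, tolerance = 1e-10)
})

test_that("permutation p values are calibrated and powered", {
  set.seed(6)
  # power: a profile whose top is loaded with the set
  scores <- sort(rnorm(120, 0, 1), decreasing = TRUE) +
    seq(2, -2, length.out = 120)
  scores <- sort(scores, decreasing = TRUE)
  names(scores) <- paste0("g", 1:120)
  top_set <- names(scores)[1:12]
  col <- gene_set_collection(list(gene_set("top", "x", top_set)))
  res <- gsea_significance(scores, col, n_perm = 1000, seed = 7)
  expect_lte(res$P.Value, 0.01)
  expect_equal(sign(res$NES), sign(res$ES))

  # calibration: random sets on a random profile reject at ~5%
  set.seed(8)
  prof <- sort(rnorm(80), decreasing = TRUE)
  names(prof) <- paste0("g", 1:80)
  rejections <- vapply(1:200, function(i) {
    rs <- gene_set_collection(list(gene_set("r", "x",
                                            sample(names(prof), 8))))
    gsea_significance(prof, rs, n_perm = 1000, seed = 1000 + i)$P.Value < 0.05
  }, logical(1))
  expect_true(abs(mean(rejections) - 0.05) < 0.02)
  expect_error(gsea_significance(prof, col, n_perm = 50), ">= 100")
})
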