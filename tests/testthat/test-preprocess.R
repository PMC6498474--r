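test_that("background adjustment subtracts the background mode and floors", {
  n <- 50
  probe_info <- data.frame(
    probe_id = paste0("p", 1:(n + 40)),
    gene = c(rep("g1", n), rep(NA, 40)),
    type = c(rep("gene", n), rep("background", 40)),
    hk = NA_character_, end = NA_character_,
    pos_frac = c(rep(0.5, n), rep(NA, 40)))
  inten <- matrix(c(rep(180, n), rep(80, 40)), ncol = 1)
  rownames(inten) <- probe_info$probe_id
  exp <- probe_experiment(inten, probe_info)
  adj <- background_adjust(exp)
  expect_equal(unname(adj$intensity[1, 1]), 100, tolerance = 2)
  expect_true(all(adj$intensity >= 1))

  # monotone (non-strict, since the floor ties low values): sorting by the
  # original intensities leaves the adjusted values non-decreasing
  g <- generate_probe_experiment(
    synthetic_design(n_genes = 80, n_de_up = 4, n_de_down = 4, seed = 1))
  a <- background_adjust(g$experiment)
  ord <- order(g$experiment$intensity[, 1])
  expect_true(all(diff(a$intensity[ord, 1]) >= 0))
})

test_that("experiments without background probes pass through with a warning", {
  g <- generate_probe_experiment(
    synthetic_design(n_genes = 40, n_de_up = 2, n_de_down = 2, seed = 2))
  keep <- g$experiment$probe_info$type != "background"
  exp <- probe_experiment(g$experiment$intensity[keep, ],
                          g$experiment$probe_info[keep, ])
  expect_warning(out <- background_adjust(exp), "skipped")
  expect_identical(out$intensity, exp$intensity)
})

test_that("quantile normalization equalizes distributions as the mean of order statistics", {
  m <- cbind(a = c(1, 3), b = c(2, 4))
  expect_equal(unname(quantile_normalize(m)),
               cbind(c(1.5, 3.5), c(1.5, 3.5)))
  set.seed(3)
  r <- matrix(rnorm(200), 50, 4)
  q <- quantile_normalize(r)
  expect_equal(unname(apply(q, 2, sort)),
               matrix(rep(sort(q[, 1]), 4), ncol = 4))
  expect_true(max(abs(colMeans(q) - mean(q))) < 1e-12)
  # idempotent
  expect_equal(quantile_normalize(q), q, tolerance = 1e-12)
  # identical columns unchanged
  same <- cbind(c(5, 1, 3), c(5, 1, 3))
  expect_equal(unname(quantile_normalize(same)), unname(same))
  # single column is the identity
  expect_equal(quantile_normalize(r[, 1, drop = FALSE]),
               r[, 1, drop = FALSE])
})

test_that("median polish absorbs exactly additive structure", {
  probe_eff <- c(0, 1, -1)
  sample_eff <- c(0, 2, 1, 3)
  m <- outer(probe_eff, rep(1, 4)) + outer(rep(1, 3), sample_eff) + 5
  rownames(m) <- paste0("p", 1:3)
  out <- summarize_median_polish(m, rep("g1", 3))
  expect_equal(unname(out["g1", ]), 5 + sample_eff, tolerance = 1e-9)

  # 2 probes x 2 samples: summaries differ by exactly the column offset
  m2 <- matrix(c(1, 2, 3, 4), 2, byrow = TRUE)  # rows [1,2] and [3,4]
  out2 <- summarize_median_polish(m2, c("g", "g"))
  expect_equal(unname(out2[1, 2] - out2[1, 1]), 1)
})

test_that("summaries ignore probe order and drop unmapped probes", {
  set.seed(4)
  m <- matrix(rnorm(60, 8), 12, 5)
  rownames(m) <- paste0("p", 1:12)
  genes <- rep(c("g1", "g2"), each = 6)
  ref <- summarize_median_polish(m, genes)
  perm <- sample(12)
  expect_equal(summarize_median_polish(m[perm, ], genes[perm]), ref,
               tolerance = 1e-9)
  expect_message(
    with_unmapped <- summarize_median_polish(rbind(m, p13 = rnorm(5)),
                                             c(genes, "unmapped")),
    "unmapped")
  expect_equal(with_unmapped, ref, tolerance = 1e-9)
})

test_that("summaries are invariant to sample column order", {
  g <- generate_probe_experiment(
    synthetic_design(n_genes = 60, n_de_up = 3, n_de_down = 3, seed = 5))
  expr <- preprocess_experiment(g$experiment)
  rev_exp <- probe_experiment(
    g$experiment$intensity[, 8:1], g$experiment$probe_info,
    groups = g$experiment$groups[8:1])
  expr_rev <- preprocess_experiment(rev_exp)
  expect_equal(expr_rev[, 8:1], expr[, ], tolerance = 1e-9,
               ignore_attr = TRUE)
})

test_that("the full chain recovers injected group effects per gene", {
  d <- synthetic_design(n_genes = 600, seed = 6)
  g <- generate_probe_experiment(d)
  expr <- preprocess_experiment(g$experiment)
  grp <- g$experiment$groups
  n1 <- sum(grp == "group1"); n2 <- sum(grp == "group2")
  est <- rowMeans(expr[, grp == "group1"]) - rowMeans(expr[, grp == "group2"])
  ss <- rowSums((expr[, grp == "group1"] -
                   rowMeans(expr[, grp == "group1"]))^2) +
    rowSums((expr[, grp == "group2"] -
               rowMeans(expr[, grp == "group2"]))^2)
  se <- sqrt(ss / (n1 + n2 - 2)) * sqrt(1 / n1 + 1 / n2)
  tr <- g$truth$genes
  de <- tr$is_de
  signed <- ifelse(tr$direction == "up", 1, -1)[de] * est[tr$gene[de]]
  # most true differential genes sit within 3 SE of the design effect and
  # the mean estimate is close to it; quantile normalization compresses
  # strong effects by a few percent when a tenth of the genes move, a known
  # property of forcing identical distributions, so exact unbiasedness is
  # not expected
  ok <- abs(signed - d$effect_log2fc) <= 3 * se[tr$gene[de]]
  expect_gte(mean(ok), 0.8)
  expect_lt(abs(mean(signed) - d$effect_log2fc), 0.1)
})
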