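make_matrix <- function(n_genes, n_per_group, noise_sd = 0.5, n_de = 0,
                        effect = 1, seed = 1) {
  d <- synthetic_design(n_genes = n_genes, n_per_group = n_per_group,
                        n_de_up = n_de, n_de_down = 0,
                        effect_log2fc = effect, noise_sd = noise_sd,
                        seed = seed)
  generate_expression_matrix(d)
}

test_that("the low-expression filter removes the stated fraction, lowest first", {
  set.seed(1)
  m <- matrix(rnorm(1000 * 4, 8), 1000, 4)
  rownames(m) <- sprintf("G%04d", 1:1000)
  out <- low_expression_filter(m, 0.25)
  expect_equal(nrow(out$kept), 750)
  expect_length(out$removed, 250)
  expect_true(max(rowMeans(m)[out$removed]) <=
                min(rowMeans(out$kept)))

  m4 <- matrix(c(1, 2, 3, 4), 4, 1, dimnames = list(letters[1:4], "s"))
  out4 <- low_expression_filter(m4, 0.25)
  expect_equal(out4$removed, "a")

  expect_equal(low_expression_filter(m, 0)$kept, m)
  expect_error(low_expression_filter(m, 1), "fraction")
})

test_that("filter ties break lexicographically by gene identifier", {
  m <- matrix(5, 4, 2, dimnames = list(c("d", "b", "a", "c"), NULL))
  out <- low_expression_filter(m, 0.5)
  expect_equal(sort(out$removed), c("a", "b"))
})

test_that("with heterogeneous variances the moderated t approaches the ordinary t", {
  set.seed(2)
  n <- 400
  # wildly different per-gene scales force the prior df towards zero
  sds <- exp(runif(n, -3, 3))
  m <- matrix(rnorm(n * 8, 0, rep(sds, 8)), n, 8)
  rownames(m) <- paste0("g", 1:n)
  grp <- factor(rep(c("a", "b"), each = 4))
  de <- moderated_t_test(m, grp)
  tt <- apply(m, 1, function(x) stats::t.test(x[1:4], x[5:8],
                                              var.equal = TRUE)$statistic)
  expect_gt(stats::cor(de$t, tt), 0.95)
  expect_lt(stats::median(abs(de$t - tt) / pmax(abs(tt), 1e-8)), 0.2)
})

test_that("with homogeneous variances the posterior variances pool", {
  set.seed(3)
  m <- matrix(rnorm(500 * 8, 0, 1), 500, 8)
  rownames(m) <- paste0("g", 1:500)
  grp <- factor(rep(c("a", "b"), each = 4))
  de <- moderated_t_test(m, grp)
  # moderated t should be near the t computed with the pooled variance
  pooled_sd <- sqrt(mean(apply(m, 1, function(x) {
    (sum((x[1:4] - mean(x[1:4]))^2) + sum((x[5:8] - mean(x[5:8]))^2)) / 6
  })))
  eff <- rowMeans(m[, 1:4]) - rowMeans(m[, 5:8])
  t_pooled <- eff / (pooled_sd * sqrt(1 / 2))
  expect_gt(stats::cor(de$t, t_pooled), 0.98)
})

test_that("type-I error is calibrated on null designs", {
  rates <- vapply(1:10, function(s) {
    gm <- make_matrix(2000, 4, noise_sd = 0.5, seed = 300 + s)
    mean(moderated_t_test(gm$expr, gm$groups)$P.Value < 0.05)
  }, numeric(1))
  expect_true(abs(mean(rates) - 0.05) < 0.02)
})

test_that("swapping group labels negates effects and preserves p values", {
  gm <- make_matrix(300, 4, n_de = 20, seed = 11)
  de1 <- moderated_t_test(gm$expr, gm$groups)
  swapped <- factor(as.character(gm$groups),
                    levels = rev(levels(gm$groups)))
  de2 <- moderated_t_test(gm$expr, swapped)
  expect_equal(de2$logFC, -de1$logFC, tolerance = 1e-12)
  expect_equal(de2$P.Value, de1$P.Value, tolerance = 1e-12)
})

test_that("B is monotone decreasing in raw p at equal residual df", {
  gm <- make_matrix(300, 4, n_de = 30, seed = 12)
  de <- moderated_t_test(gm$expr, gm$groups)
  ord <- order(de$P.Value)
  expect_true(all(diff(de$B[ord]) <= 1e-10))
  expect_true(all(de$adj.P.Val >= de$P.Value))
})

test_that("group size and input validation errors are raised", {
  gm <- make_matrix(50, 2, seed = 13)
  expect_error(moderated_t_test(gm$expr, c("a", "a", "a", "b")),
               "at least 2 samples")
  expect_error(moderated_t_test(gm$expr, rep("a", 4)), "two levels")
})

test_that("BH adjustment matches the brute-force min-over-suffix oracle", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.2), 0.2)
  expect_equal(bh_adjust(rep(0.07, 5)), rep(0.07, 5))
  set.seed(14)
  for (i in 1:20) {
    p <- switch(1 + i %% 3,
                runif(sample(1:40, 1)),
                round(runif(20), 2),          # heavy ties
                c(0, 1, runif(10)))           # boundary values
    expect_equal(bh_adjust(p), brute_bh(p), tolerance = 1e-12)
  }
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("power and FDR hold on the stated recovery design", {
  # effect 1.0 log2, per-probe noise 0.5, 4 vs 4, full probe-level chain
  sens <- fdp <- numeric(10)
  for (s in 1:10) {
    d <- synthetic_design(n_genes = 600, noise_sd = 0.5, n_de_up = 30,
                          n_de_down = 30, seed = 400 + s)
    g <- generate_probe_experiment(d)
    expr <- preprocess_experiment(g$experiment)
    de <- run_de(expr, g$experiment$groups)
    sig <- de$gene[!is.na(de$adj.P.Val) & de$adj.P.Val < 0.05]
    true_de <- g$truth$genes$gene[g$truth$genes$is_de]
    sens[s] <- mean(true_de %in% sig)
    fdp[s] <- if (length(sig)) mean(!(sig %in% true_de)) else 0
  }
  expect_gte(mean(sens), 0.8)
  expect_lte(mean(fdp), 0.1)
})
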