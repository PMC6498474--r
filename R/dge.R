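#' Differential-expression configuration
#'
#' The inclusion and ranking rules applied to every comparison: genes enter a
#' set if their Benjamini-Hochberg adjusted p value is below
#' `fdr_threshold`, at most `max_genes_per_set` genes are kept after ranking
#' by the B score, the `low_expression_fraction` of genes with the lowest
#' average expression is removed before testing, and `prior_de_proportion` is
#' the prior probability of differential expression used by the B score.
#'
#' @param fdr_threshold FDR cutoff for set inclusion, in (0, 1).
#' @param max_genes_per_set Cap on genes per direction-split set.
#' @param low_expression_fraction Fraction of lowest-expressed genes removed
#'   before testing, in \[0, 1).
#' @param prior_de_proportion Prior proportion of differentially expressed
#'   genes for the posterior-odds (B) computation.
#' @return An object of class `de_config`.
#' @export
de_config <- function(fdr_threshold = 0.05, max_genes_per_set = 300,
                      low_expression_fraction = 0.25,
                      prior_de_proportion = 0.01) {
  if (!is_scalar_number(fdr_threshold) || fdr_threshold <= 0 ||
      fdr_threshold >= 1) {
    stopf("'fdr_threshold' must be in (0, 1)")
  }
  if (!is_count(max_genes_per_set)) {
    stopf("'max_genes_per_set' must be a positive integer")
  }
  if (!is_scalar_number(low_expression_fraction) ||
      low_expression_fraction < 0 || low_expression_fraction >= 1) {
    stopf("'low_expression_fraction' must be in [0, 1)")
  }
  if (!is_scalar_number(prior_de_proportion) || prior_de_proportion <= 0 ||
      prior_de_proportion >= 1) {
    stopf("'prior_de_proportion' must be in (0, 1)")
  }
  structure(list(fdr_threshold = fdr_threshold,
                 max_genes_per_set = as.integer(max_genes_per_set),
                 low_expression_fraction = low_expression_fraction,
                 prior_de_proportion = prior_de_proportion),
            class = "de_config")
}

#' Remove the lowest-expressed genes
#'
#' Ranks genes by mean log2 expression across all samples and removes the
#' `floor(fraction * n_genes)` lowest, breaking ties by gene identifier in
#' lexicographic order so the result is deterministic. Applied per
#' comparison, before variance moderation, so that near-background genes do
#' not dilute the prior.
#'
#' @param mat Gene x sample log2 expression matrix with gene row names.
#' @param fraction Fraction to remove, in \[0, 1).
#' @return A list with `kept` (the filtered matrix) and `removed` (character
#'   vector of removed gene identifiers).
#' @export
low_expression_filter <- function(mat, fraction = 0.25) {
  mat <- as.matrix(mat)
  if (!is_scalar_number(fraction) || fraction < 0 || fraction >= 1) {
    stopf("'fraction' must be in [0, 1)")
  }
  if (is.null(rownames(mat))) stopf("'mat' must have gene row names")
  n_drop <- floor(fraction * nrow(mat))
  if (n_drop == 0L) {
    return(list(kept = mat, removed = character()))
  }
  ord <- order(rowMeans(mat), rownames(mat))
  removed <- rownames(mat)[ord[seq_len(n_drop)]]
  list(kept = mat[!rownames(mat) %in% removed, , drop = FALSE],
       removed = removed)
}

#' Moderated two-group differential expression
#'
#' Empirical-Bayes moderated t-test between two groups: per-gene residual
#' variances are shrunk towards a prior estimated by moment matching on the
#' log variances, the moderated t uses the shrunken variance with augmented
#' degrees of freedom, and the B score is the log posterior odds of
#' differential expression under the configured prior proportion. Effects are
#' reported as group 1 minus group 2 (the first factor level minus the
#' second), so swapping the level order negates every effect and leaves p
#' values unchanged. Backed by [limma::lmFit()] and [limma::eBayes()], whose
#' `fitFDist` prior estimation is exactly the moment-matching construction.
#' Genes with zero residual variance are counted and reported via a message
#' (their variance is handled by the shrinkage prior).
#'
#' @param mat Gene x sample log2 expression matrix (already filtered).
#' @param groups Factor (or coercible) with exactly two levels, each with at
#'   least 2 samples.
#' @param config A [de_config()].
#' @param df_lost Residual degrees of freedom already consumed upstream of
#'   the test — e.g. the number of surrogate variables whose fitted
#'   contribution was subtracted by [remove_surrogates()]. The residual
#'   variance is rescaled to its unbiased value and the residual df reduced
#'   accordingly, so p values stay calibrated after correction.
#' @return A data frame (one row per gene) with columns `gene`, `logFC`,
#'   `AveExpr`, `t`, `df.total`, `P.Value`, `adj.P.Val`, `B`, `filtered`.
#' @export
moderated_t_test <- function(mat, groups, config = de_config(),
                             df_lost = 0) {
  mat <- as.matrix(mat)
  stopifnot(inherits(config, "de_config"))
  groups <- as.factor(groups)
  groups <- droplevels(groups)
  if (nlevels(groups) != 2L) {
    stopf("'groups' must have exactly two levels, got %d", nlevels(groups))
  }
  if (length(groups) != ncol(mat)) {
    stopf("'groups' length must equal the number of samples")
  }
  if (any(table(groups) < 2L)) {
    stopf("each group needs at least 2 samples")
  }
  if (is.null(rownames(mat))) {
    rownames(mat) <- paste0("g", seq_len(nrow(mat)))
  }
  design <- stats::model.matrix(~ 0 + groups)
  colnames(design) <- c("g1", "g2")
  fit <- limma::lmFit(mat, design)
  n_zero_var <- sum(fit$sigma == 0, na.rm = TRUE)
  if (n_zero_var > 0) {
    message(sprintf(
      "moderated_t_test: %d gene(s) with zero residual variance (handled by the shrinkage prior)",
      n_zero_var))
  }
  contr <- limma::makeContrasts(g1 - g2, levels = design)
  fit <- limma::contrasts.fit(fit, contr)
  if (df_lost > 0) {
    d <- fit$df.residual
    if (any(d - df_lost < 1)) {
      stopf("df_lost (%g) leaves no residual degrees of freedom", df_lost)
    }
    fit$sigma <- fit$sigma * sqrt(d / (d - df_lost))
    fit$df.residual <- d - df_lost
  }
  fit <- limma::eBayes(fit, proportion = config$prior_de_proportion)
  tab <- limma::topTable(fit, coef = 1, number = Inf, sort.by = "none")
  data.frame(gene = rownames(mat), logFC = tab$logFC, AveExpr = tab$AveExpr,
             t = tab$t, df.total = fit$df.total,
             P.Value = tab$P.Value, adj.P.Val = tab$adj.P.Val, B = tab$B,
             filtered = FALSE, row.names = NULL, stringsAsFactors = FALSE)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: with p values sorted ascending, the i-th adjusted
#' value is `min over j >= i of p_(j) * m / j`, capped at 1, returned in the
#' original order. Backed by [stats::p.adjust()] with input validation.
#'
#' @param pvalues Numeric vector of p values in \[0, 1\].
#' @return Adjusted p values, same length and order.
#' @export
bh_adjust <- function(pvalues) {
  if (!is.numeric(pvalues)) stopf("'pvalues' must be numeric")
  if (any(!is.finite(pvalues)) || any(pvalues < 0 | pvalues > 1)) {
    stopf("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Run the differential-expression stage on a comparison
#'
#' Convenience wrapper chaining [low_expression_filter()] and
#' [moderated_t_test()]; filtered genes are appended to the result with
#' `filtered = TRUE` and `NA` statistics so the full gene universe remains
#' visible.
#'
#' @inheritParams moderated_t_test
#' @return A data frame as in [moderated_t_test()], with removed genes
#'   flagged `filtered = TRUE`.
#' @export
run_de <- function(mat, groups, config = de_config(), df_lost = 0) {
  stopifnot(inherits(config, "de_config"))
  flt <- low_expression_filter(mat, config$low_expression_fraction)
  res <- moderated_t_test(flt$kept, groups, config, df_lost = df_lost)
  if (length(flt$removed)) {
    res <- rbind(res,
                 data.frame(gene = flt$removed, logFC = NA_real_,
                            AveExpr = rowMeans(mat)[flt$removed],
                            t = NA_real_, df.total = NA_real_,
                            P.Value = NA_real_, adj.P.Val = NA_real_,
                            B = NA_real_, filtered = TRUE,
                            row.names = NULL, stringsAsFactors = FALSE))
  }
  res
}
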