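#' Estimate surrogate variables of technical variation
#'
#' Detects latent technical factors (batch effects) in a two-group expression
#' matrix and caps the number retained at `max_sv` to avoid overcorrection.
#' The expression matrix is first residualized against the group labels, so
#' the contrast of interest is protected; the residual matrix is then
#' decomposed by SVD and the number of significant components is chosen by
#' permutation parallel analysis: each observed singular value receives a
#' permutation p value against its null distribution, obtained by
#' independently permuting each gene's values across samples and
#' residualizing the permuted matrix (`n_perm` draws), and leading
#' components are kept while that p value is at or below
#' `1 - null_quantile`. Surrogate values start from the right singular
#' vectors of the retained components and are then augmented with their
#' estimated group-aligned component (recovered from the per-gene loadings,
#' so that a batch partially aligned with the groups is fully represented),
#' and finally orthonormalized. The result is deterministic given `seed`.
#'
#' @param mat Gene x sample log2 expression matrix (at least 4 samples).
#' @param groups Two-level factor of group labels.
#' @param max_sv Maximum number of surrogate variables (default 2).
#' @param n_perm Number of row-permutation null draws.
#' @param seed Integer seed for the permutations.
#' @param null_quantile Null percentile a singular value must exceed.
#' @return An object of class `surrogate_result`: a list with `n_sv`,
#'   `surrogates` (samples x `n_sv` matrix, possibly zero columns),
#'   `corrected` (the matrix after [remove_surrogates()]), and `singular`
#'   (observed singular values and their null thresholds, for inspection).
#' @export
estimate_surrogates <- function(mat, groups, max_sv = 2, n_perm = 20,
                                seed = 1, null_quantile = 0.95) {
  mat <- as.matrix(mat)
  if (!is.numeric(max_sv) || length(max_sv) != 1L || max_sv < 0 ||
      max_sv != floor(max_sv)) {
    stopf("'max_sv' must be a non-negative integer")
  }
  groups <- droplevels(as.factor(groups))
  if (nlevels(groups) != 2L) stopf("'groups' must have exactly two levels")
  if (ncol(mat) < 4L) stopf("surrogate estimation needs at least 4 samples")
  if (length(groups) != ncol(mat)) {
    stopf("'groups' length must equal the number of samples")
  }

  # residualize against the group labels
  residualize <- function(m) {
    means <- vapply(levels(groups), function(g) {
      rowMeans(m[, groups == g, drop = FALSE])
    }, numeric(nrow(m)))
    m - means[, as.integer(groups), drop = FALSE]
  }
  resid <- residualize(mat)

  n <- ncol(mat)
  max_rank <- min(nrow(mat), n - nlevels(groups))
  sv <- svd(resid, nu = 0)
  d_obs <- sv$d

  n_sv <- 0L
  thr <- rep(NA_real_, length(d_obs))
  if (max_sv > 0 && max_rank > 0) {
    null_d <- with_seed(seed, {
      t(vapply(seq_len(n_perm), function(b) {
        # permute each gene's values across samples on the raw matrix, then
        # residualize: under the null this reproduces the observed
        # distribution exactly, whereas permuting the residuals themselves
        # breaks their within-group zero-sum constraints and deflates the
        # null singular values
        perm <- matrix(mat[order(row(mat), stats::runif(length(mat)))],
                       nrow = nrow(mat), byrow = TRUE)
        svd(residualize(perm), nu = 0, nv = 0)$d
      }, numeric(length(d_obs))))
    })
    thr <- apply(null_d, 2, stats::quantile, probs = null_quantile,
                 names = FALSE)
    # keep a component when its permutation p value is at or below
    # 1 - null_quantile: p = (1 + #{null >= observed}) / (1 + n_perm)
    alpha <- 1 - null_quantile
    while (n_sv < min(max_sv, max_rank)) {
      j <- n_sv + 1L
      p_j <- (1 + sum(null_d[, j] >= d_obs[j])) / (1 + n_perm)
      if (p_j > alpha) break
      n_sv <- n_sv + 1L
    }
  }
  surrogates <- sv$v[, seq_len(n_sv), drop = FALSE]
  if (n_sv > 0) {
    # Reconstruct each surrogate's group-aligned component. The residual
    # right singular vector only spans the part of a batch vector that is
    # orthogonal to the groups; its aligned part is identifiable from the
    # genes: regressing per-gene group differences on the per-gene residual
    # loadings estimates how much of the apparent group effect rides on the
    # latent factor. Without this step a batch partially aligned with the
    # groups would stay partially confounded after removal.
    cvec <- ifelse(groups == levels(groups)[1], 0.5, -0.5)
    beta <- rowMeans(mat[, groups == levels(groups)[1], drop = FALSE]) -
      rowMeans(mat[, groups == levels(groups)[2], drop = FALSE])
    for (j in seq_len(n_sv)) {
      delta <- as.numeric(resid %*% sv$v[, j])
      slope <- stats::cov(beta, delta) / stats::var(delta)
      surrogates[, j] <- sv$v[, j] + slope * cvec
    }
    # orthonormalize among themselves; the removal step is invariant to
    # basis changes within the surrogate span
    qq <- qr.Q(qr(surrogates))
    for (j in seq_len(n_sv)) {
      if (sum(qq[, j] * sv$v[, j]) < 0) qq[, j] <- -qq[, j]
    }
    surrogates <- qq
    colnames(surrogates) <- paste0("SV", seq_len(n_sv))
  }
  rownames(surrogates) <- colnames(mat)
  corrected <- remove_surrogates(mat, groups, surrogates)
  structure(list(n_sv = n_sv, surrogates = surrogates,
                 corrected = corrected,
                 singular = data.frame(component = seq_along(d_obs),
                                       singular_value = d_obs,
                                       null_threshold = thr)),
            class = "surrogate_result")
}

#' @export
print.surrogate_result <- function(x, ...) {
  cat(sprintf("<surrogate_result> %d surrogate variable(s) over %d sample(s)\n",
              x$n_sv, nrow(x$surrogates)))
  invisible(x)
}

#' Remove surrogate-variable contributions from expression
#'
#' Per gene, fits expression on the group indicator plus the surrogate
#' columns by least squares and subtracts only the fitted surrogate
#' contribution, leaving the group effect (and intercept) untouched. With
#' zero surrogates this is the identity; applying it twice with the same
#' surrogates is idempotent. A surrogate that is collinear with the group
#' design (within rank tolerance) cannot be separated from the effect of
#' interest and is dropped with a warning.
#'
#' @param mat Gene x sample log2 expression matrix.
#' @param groups Two-level factor of group labels.
#' @param surrogates Samples x k matrix of surrogate values (k may be 0), or
#'   a [estimate_surrogates()] result.
#' @return The corrected matrix, same dimensions and dimnames as `mat`.
#' @export
remove_surrogates <- function(mat, groups, surrogates) {
  mat <- as.matrix(mat)
  if (inherits(surrogates, "surrogate_result")) {
    surrogates <- surrogates$surrogates
  }
  surrogates <- as.matrix(surrogates)
  if (ncol(surrogates) == 0L) return(mat)
  if (nrow(surrogates) != ncol(mat)) {
    stopf("surrogate rows (%d) must match sample count (%d)",
          nrow(surrogates), ncol(mat))
  }
  groups <- droplevels(as.factor(groups))
  base <- stats::model.matrix(~groups)

  # drop surrogates collinear with the group design
  keep <- logical(ncol(surrogates))
  for (j in seq_len(ncol(surrogates))) {
    r <- stats::lm.fit(base, surrogates[, j])$residuals
    keep[j] <- sqrt(sum(r^2)) > 1e-8 * max(1, sqrt(sum(surrogates[, j]^2)))
  }
  if (!all(keep)) {
    warnf("dropped %d surrogate(s) collinear with the group design",
          sum(!keep))
    surrogates <- surrogates[, keep, drop = FALSE]
    if (ncol(surrogates) == 0L) return(mat)
  }

  X <- cbind(base, surrogates)
  coefs <- qr.coef(qr(X), t(mat))
  sv_rows <- seq.int(ncol(base) + 1L, ncol(X))
  fitted_sv <- surrogates %*% coefs[sv_rows, , drop = FALSE]
  mat - t(fitted_sv)
}
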