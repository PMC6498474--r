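#' Quality-control thresholds
#'
#' The standard acceptance thresholds for 3' expression arrays: pairwise
#' differences in average background no greater than 20 intensity units,
#' scale factors within 3-fold of one another, percent-present differences no
#' greater than 10 percentage points, 3'/5' degradation ratios of at most
#' 1.25 for the GAPDH-analogue control and 3.0 for the beta-actin analogue,
#' per-sample median NUSE at most 1.1, and per-sample RLE spread (IQR) at
#' most 0.2 log2 units. Pairwise metrics are assessed as deviation from the
#' series median (see [apply_battery()]); the others are absolute.
#'
#' @param max_background_diff Intensity units, deviation from series median.
#' @param max_scale_factor_fold Fold change versus the series median.
#' @param max_percent_present_diff Percentage points versus the series median.
#' @param max_ratio_hk1,max_ratio_hk2 3'/5' ratio caps for the two
#'   housekeeping controls.
#' @param max_median_nuse Cap on the per-sample median NUSE.
#' @param max_rle_spread Cap on the per-sample RLE interquartile range (log2).
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(max_background_diff = 20,
                          max_scale_factor_fold = 3,
                          max_percent_present_diff = 10,
                          max_ratio_hk1 = 1.25,
                          max_ratio_hk2 = 3.0,
                          max_median_nuse = 1.1,
                          max_rle_spread = 0.2) {
  vals <- c(max_background_diff, max_scale_factor_fold,
            max_percent_present_diff, max_ratio_hk1, max_ratio_hk2,
            max_median_nuse, max_rle_spread)
  if (!all(is.finite(vals)) || any(vals <= 0)) {
    stopf("all QC thresholds must be strictly positive")
  }
  structure(list(max_background_diff = max_background_diff,
                 max_scale_factor_fold = max_scale_factor_fold,
                 max_percent_present_diff = max_percent_present_diff,
                 max_ratio_hk1 = max_ratio_hk1,
                 max_ratio_hk2 = max_ratio_hk2,
                 max_median_nuse = max_median_nuse,
                 max_rle_spread = max_rle_spread),
            class = "qc_thresholds")
}

#' Single-array quality metrics
#'
#' Computes, for one sample of a probe-level experiment: the average
#' background (mean of the designated background probes), the scale factor
#' (500 divided by the 2%-trimmed mean of the non-background probe
#' intensities — only its ratio across samples matters for the battery), the
#' percentage of probe sets called present (those whose median probe
#' intensity exceeds the 95th percentile of the background-probe
#' intensities; a background-quantile detection call standing in for the
#' classical detection p-value, preserving the metric's role of comparability
#' across a series), and the two housekeeping 3'/5' ratios (mean 3'-end
#' control intensity over mean 5'-end control intensity; values near 1
#' indicate intact RNA).
#'
#' @param exp A [probe_experiment()].
#' @param sample Sample index or name.
#' @param sf_target Scale-factor target constant.
#' @param sf_trim Trim fraction for the scale-factor trimmed mean.
#' @param present_quantile Background quantile used for the present call.
#' @return A list with `average_background`, `scale_factor`,
#'   `percent_present`, `ratio_hk1`, `ratio_hk2`.
#' @export
single_array_metrics <- function(exp, sample, sf_target = 500,
                                 sf_trim = 0.02, present_quantile = 0.95) {
  stopifnot(inherits(exp, "probe_experiment"))
  x <- exp$intensity[, sample]
  info <- exp$probe_info
  is_bg <- info$type == "background"
  if (!any(is_bg)) {
    stopf("missing control annotation: no background probes in probe_info")
  }
  hk_ids <- sort(unique(info$hk[info$type == "control" & !is.na(info$hk)]))
  if (length(hk_ids) < 2L) {
    stopf("missing control annotation: need two housekeeping controls with 3'/5' labels, found %d",
          length(hk_ids))
  }
  bg <- x[is_bg]
  avg_bg <- mean(bg)
  sf <- sf_target / mean(x[!is_bg], trim = sf_trim)

  gene_probes <- info$type == "gene"
  med_by_gene <- tapply(x[gene_probes], info$gene[gene_probes], stats::median)
  thr <- stats::quantile(bg, present_quantile, names = FALSE)
  pp <- 100 * mean(med_by_gene > thr)

  ratio <- vapply(hk_ids[1:2], function(h) {
    sel <- info$type == "control" & !is.na(info$hk) & info$hk == h
    three <- x[sel & info$end == "3prime"]
    five <- x[sel & info$end == "5prime"]
    if (!length(three) || !length(five)) {
      stopf("missing control annotation: housekeeping '%s' lacks 3'/5'-labelled probes", h)
    }
    mean(three) / mean(five)
  }, numeric(1))

  list(average_background = avg_bg, scale_factor = sf,
       percent_present = pp, ratio_hk1 = ratio[[1]], ratio_hk2 = ratio[[2]])
}

#' Relative log expression (RLE)
#'
#' For gene g and sample i, the RLE deviation is the log2 expression minus
#' the across-sample median for that gene. Because most genes are assumed
#' unchanged across a series, these deviations should be centred near 0 with
#' similar, small spread in every sample. Per sample, the median deviation and
#' the interquartile range of the deviations are returned; the battery flags
#' on the spread only (no standard numeric threshold exists for the median,
#' which is reported for inspection).
#'
#' @param mat Gene x sample matrix of log2 expression (at least 3 samples).
#' @return A data frame with columns `sample`, `rle_median`, `rle_spread`.
#' @export
rle_stats <- function(mat) {
  mat <- as.matrix(mat)
  if (ncol(mat) < 3L) {
    stopf("RLE needs at least 3 samples (across-sample median is degenerate)")
  }
  d <- mat - row_medians(mat)
  data.frame(sample = colnames(mat) %||% paste0("S", seq_len(ncol(mat))),
             rle_median = apply(d, 2, stats::median),
             rle_spread = apply(d, 2, stats::IQR),
             row.names = NULL, stringsAsFactors = FALSE)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# Median-polish every gene of a probe-level experiment on the log2 scale.
# Returns the summarized expression (overall + sample effect), the per-gene
# per-sample standard-error proxy (RMS residual / sqrt(n probes)), and the
# number of genes excluded for having fewer than `min_probes` probes.
polish_genes <- function(exp, min_probes = 1L, maxiter = 10L, eps = 0.01) {
  stopifnot(inherits(exp, "probe_experiment"))
  info <- exp$probe_info
  sel <- info$type == "gene"
  l2 <- log2(exp$intensity[sel, , drop = FALSE])
  polish_matrix(l2, info$gene[sel], min_probes = min_probes,
                maxiter = maxiter, eps = eps)
}

polish_matrix <- function(l2, genes, min_probes = 1L, maxiter = 10L,
                          eps = 0.01) {
  idx <- split(seq_len(nrow(l2)), genes)
  n_probes <- lengths(idx)
  excluded <- sum(n_probes < min_probes)
  idx <- idx[n_probes >= min_probes]
  n_smp <- ncol(l2)
  expr <- matrix(NA_real_, length(idx), n_smp,
                 dimnames = list(names(idx), colnames(l2)))
  se <- expr
  for (i in seq_along(idx)) {
    sub <- l2[idx[[i]], , drop = FALSE]
    if (nrow(sub) == 1L) {
      expr[i, ] <- sub
      se[i, ] <- 0
      next
    }
    mp <- stats::medpolish(sub, eps = eps, maxiter = maxiter,
                           trace.iter = FALSE)
    expr[i, ] <- mp$overall + mp$col
    se[i, ] <- sqrt(colMeans(mp$residuals^2)) / sqrt(nrow(sub))
  }
  list(expr = expr, se = se, excluded = excluded)
}

#' Normalized unscaled standard error (NUSE)
#'
#' Fits, per gene, the additive model log2 intensity = overall + probe effect
#' + sample effect by median polish, takes the per-gene per-sample
#' standard-error proxy (root-mean-square residual over the gene's probes in
#' that sample, divided by the square root of the probe count), normalizes
#' each gene's proxies by their across-sample median, and reports the median
#' over genes per sample. Clean samples yield values near 1; values above 1.1
#' indicate poor quality. Genes with fewer than 2 probes carry no residual
#' information and are excluded (a message reports the count); the metric is
#' invariant to adding a constant to one sample's log2 intensities, which is
#' absorbed by the sample effect.
#'
#' @param exp A [probe_experiment()] with at least 3 samples.
#' @return A data frame with columns `sample`, `median_nuse`.
#' @export
nuse <- function(exp) {
  stopifnot(inherits(exp, "probe_experiment"))
  if (n_samples(exp) < 3L) stopf("NUSE needs at least 3 samples")
  pol <- polish_genes(exp, min_probes = 2L)
  if (pol$excluded > 0) {
    message(sprintf("NUSE: excluded %d gene(s) with fewer than 2 probes",
                    pol$excluded))
  }
  nuse_from_se(pol$se, colnames(exp$intensity))
}

nuse_from_se <- function(se, sample_names) {
  med <- row_medians(se)
  ok <- med > 0
  norm <- se[ok, , drop = FALSE] / med[ok]
  data.frame(sample = sample_names,
             median_nuse = apply(norm, 2, stats::median),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Full quality-control report for an array series
#'
#' Computes every metric the battery uses — single-array metrics per sample
#' ([single_array_metrics()]), per-sample median NUSE from one median-polish
#' pass over all genes, and RLE statistics on the summarized expression from
#' that same pass — and applies the combined pass/fail battery
#' ([apply_battery()]).
#'
#' @param exp A [probe_experiment()] with at least 3 samples.
#' @param thresholds A [qc_thresholds()].
#' @return A data frame, one row per sample, with all metric columns plus
#'   `flags` (comma-separated failed metric names, empty if none) and
#'   `verdict` (`"pass"` or `"fail"`).
#' @export
qc_report <- function(exp, thresholds = qc_thresholds()) {
  stopifnot(inherits(exp, "probe_experiment"))
  if (n_samples(exp) < 3L) stopf("the QC battery needs at least 3 samples")
  single <- lapply(seq_len(n_samples(exp)), function(i) {
    as.data.frame(single_array_metrics(exp, i))
  })
  rep <- do.call(rbind, single)
  rep <- cbind(sample = colnames(exp$intensity), rep,
               stringsAsFactors = FALSE)
  pol <- polish_genes(exp, min_probes = 2L)
  rep$median_nuse <- nuse_from_se(pol$se, rep$sample)$median_nuse
  rle <- rle_stats(pol$expr)
  rep$rle_median <- rle$rle_median
  rep$rle_spread <- rle$rle_spread
  apply_battery(rep, thresholds)
}

#' Apply the combined quality pass/fail battery
#'
#' Pairwise metrics (average background, scale factor, percent present) flag
#' a sample whose value deviates from the series median by more than the
#' threshold — as a fold change for the scale factor, absolutely otherwise.
#' (Deviation from the series median, rather than all-pairs comparison, is
#' used as the reference: an all-pairs rule flags both members of a
#' discordant pair, while the median reference isolates the outlier.)
#' Absolute metrics (the two 3'/5' ratios, median NUSE, RLE spread) flag
#' directly against their caps. The verdict is `"fail"` iff any flag is
#' raised.
#'
#' @param reports Data frame with one row per sample of the series and
#'   columns `average_background`, `scale_factor`, `percent_present`,
#'   `ratio_hk1`, `ratio_hk2`, `median_nuse`, `rle_spread` (as produced
#'   within [qc_report()]).
#' @param thresholds A [qc_thresholds()].
#' @return `reports` with `flags` and `verdict` columns added.
#' @export
apply_battery <- function(reports, thresholds = qc_thresholds()) {
  stopifnot(is.data.frame(reports), inherits(thresholds, "qc_thresholds"))
  need <- c("average_background", "scale_factor", "percent_present",
            "ratio_hk1", "ratio_hk2", "median_nuse", "rle_spread")
  miss <- setdiff(need, names(reports))
  if (length(miss)) {
    stopf("reports is missing metric column(s): %s",
          paste(miss, collapse = ", "))
  }
  bg_dev <- abs(reports$average_background -
                  stats::median(reports$average_background))
  sf_med <- stats::median(reports$scale_factor)
  sf_fold <- pmax(reports$scale_factor / sf_med, sf_med / reports$scale_factor)
  pp_dev <- abs(reports$percent_present -
                  stats::median(reports$percent_present))
  flag_mat <- cbind(
    average_background = bg_dev > thresholds$max_background_diff,
    scale_factor = sf_fold > thresholds$max_scale_factor_fold,
    percent_present = pp_dev > thresholds$max_percent_present_diff,
    ratio_hk1 = reports$ratio_hk1 > thresholds$max_ratio_hk1,
    ratio_hk2 = reports$ratio_hk2 > thresholds$max_ratio_hk2,
    median_nuse = reports$median_nuse > thresholds$max_median_nuse,
    rle_spread = reports$rle_spread > thresholds$max_rle_spread)
  reports$flags <- apply(flag_mat, 1, function(f) {
    paste(colnames(flag_mat)[f], collapse = ",")
  })
  reports$verdict <- ifelse(nzchar(reports$flags), "fail", "pass")
  reports
}
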