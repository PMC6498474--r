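#' Design of a synthetic two-group probe-level experiment
#'
#' Describes the ground-truth generative model used by
#' [generate_probe_experiment()]: a two-group design with a chosen number of
#' truly up-/downregulated genes, per-probe affinities, optional latent batch
#' factors, and residual noise. Intensities are generated on the natural scale
#' as `2^(gene effect + probe affinity + group effect + batch + noise)` plus
#' an additive optical background, which reproduces the structure that the
#' quality metrics (background, scale factor, percent present, 3'/5' ratios,
#' RLE, NUSE) respond to without modelling scanner physics.
#'
#' Defaults describe a small but realistic array series: 1000 genes with 11
#' probes each (the probe count of the classic 3' expression chips), 4 samples
#' per group, 50 genes up- and 50 downregulated at 1 log2 unit, and residual
#' per-probe noise of 0.25 log2 units, a typical post-normalization residual
#' scale at which a clean array also passes the standard quality thresholds.
#'
#' @param n_genes Number of genes.
#' @param probes_per_gene Probes per gene (at least 3).
#' @param n_per_group Samples per group (two groups).
#' @param n_de_up,n_de_down Numbers of truly up-/downregulated genes
#'   (up = higher in group 1). Their sum must not exceed `n_genes`.
#' @param effect_log2fc True group difference for differential genes, in log2
#'   units.
#' @param noise_sd Residual (per probe, per sample) standard deviation, log2
#'   units; must be positive.
#' @param n_batch_factors Number of injected latent technical factors.
#' @param batch_sd Per-gene batch effect scale (log2 units).
#' @param seed Integer seed; equal seeds give bit-identical experiments.
#' @return An object of class `synthetic_design`.
#' @export
synthetic_design <- function(n_genes = 1000, probes_per_gene = 11,
                             n_per_group = 4, n_de_up = 50, n_de_down = 50,
                             effect_log2fc = 1.0, noise_sd = 0.25,
                             n_batch_factors = 0, batch_sd = 0,
                             seed = 1) {
  for (nm in c("n_genes", "probes_per_gene", "n_per_group")) {
    if (!is_count(get(nm))) stopf("'%s' must be a positive integer", nm)
  }
  if (probes_per_gene < 3) stopf("'probes_per_gene' must be at least 3")
  for (nm in c("n_de_up", "n_de_down", "n_batch_factors")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && v >= 0 && v == floor(v))) {
      stopf("'%s' must be a non-negative integer", nm)
    }
  }
  if (n_de_up + n_de_down > n_genes) {
    stopf("n_de_up + n_de_down must not exceed n_genes")
  }
  if (!is_scalar_number(noise_sd) || noise_sd <= 0) {
    stopf("'noise_sd' must be positive")
  }
  if (!is_scalar_number(effect_log2fc)) stopf("'effect_log2fc' must be a number")
  if (!is_scalar_number(batch_sd) || batch_sd < 0) {
    stopf("'batch_sd' must be non-negative")
  }
  structure(list(n_genes = as.integer(n_genes),
                 probes_per_gene = as.integer(probes_per_gene),
                 n_per_group = as.integer(n_per_group),
                 n_de_up = as.integer(n_de_up),
                 n_de_down = as.integer(n_de_down),
                 effect_log2fc = effect_log2fc, noise_sd = noise_sd,
                 n_batch_factors = as.integer(n_batch_factors),
                 batch_sd = batch_sd, seed = as.integer(seed)),
            class = "synthetic_design")
}

#' Specify an injected array failure
#'
#' The five failure modes mirror the classes of array damage the quality
#' battery is designed to catch: elevated optical background
#' (`high_background`), global mis-scaling (`bad_scale`), loss of detectable
#' signal (`low_percent_present`), RNA degradation biasing intensity towards
#' the 3' end of transcripts (`degraded_3prime`), and inflated residual noise
#' (`inflated_noise`).
#'
#' Severity is a positive scalar: background shifts by `20 * severity`
#' intensity units, mis-scaling multiplies the array by `2^severity`, signal
#' loss silences `min(0.9, 0.15 * severity)` of genes, degradation applies a
#' multiplicative gradient of `2^(-severity * (1 - position))` along the
#' 5'-to-3' probe position (so the housekeeping 3'/5' ratio grows roughly as
#' `2^(0.8 * severity)`), and noise inflation multiplies the residual SD by
#' `severity`.
#'
#' @param sample Index of the affected sample.
#' @param mode One of `"high_background"`, `"bad_scale"`,
#'   `"low_percent_present"`, `"degraded_3prime"`, `"inflated_noise"`.
#' @param severity Positive scalar.
#' @return An object of class `qc_failure`.
#' @export
qc_failure <- function(sample,
                       mode = c("high_background", "bad_scale",
                                "low_percent_present", "degraded_3prime",
                                "inflated_noise"),
                       severity = 2) {
  if (!is_count(sample)) stopf("'sample' must be a positive integer index")
  mode <- match.arg(mode)
  if (!is_scalar_number(severity) || severity <= 0) {
    stopf("'severity' must be a positive scalar")
  }
  structure(list(sample = as.integer(sample), mode = mode,
                 severity = severity),
            class = "qc_failure")
}

#' Construct a probe-level experiment container
#'
#' @param intensity Numeric probes x samples matrix of strictly positive
#'   intensities on the natural scale, with probe row names.
#' @param probe_info Data frame with one row per probe: `probe_id`, `gene`
#'   (gene identifier for regular probes, `NA` for controls), `type` (one of
#'   `"gene"`, `"control"`, `"background"`), `hk` (housekeeping transcript id
#'   for control probes), `end` (`"5prime"`, `"middle"`, `"3prime"` for
#'   control probes), `pos_frac` (relative 5'-to-3' position in `[0, 1]`).
#' @param groups Optional factor of sample group labels.
#' @return An object of class `probe_experiment`.
#' @export
probe_experiment <- function(intensity, probe_info, groups = NULL) {
  intensity <- as.matrix(intensity)
  if (!is.numeric(intensity)) stopf("'intensity' must be numeric")
  if (any(!is.finite(intensity)) || any(intensity <= 0)) {
    stopf("all intensities must be finite and strictly positive")
  }
  req <- c("probe_id", "gene", "type", "pos_frac")
  if (!all(req %in% names(probe_info))) {
    stopf("probe_info must contain columns: %s", paste(req, collapse = ", "))
  }
  if (nrow(probe_info) != nrow(intensity)) {
    stopf("probe_info rows (%d) must match intensity rows (%d)",
          nrow(probe_info), nrow(intensity))
  }
  if (!all(probe_info$type %in% c("gene", "control", "background"))) {
    stopf("probe type must be 'gene', 'control' or 'background'")
  }
  regular <- probe_info$type == "gene"
  if (any(is.na(probe_info$gene[regular]))) {
    stopf("every non-control probe must map to exactly one gene")
  }
  if (is.null(colnames(intensity))) {
    colnames(intensity) <- paste0("S", seq_len(ncol(intensity)))
  }
  if (!is.null(groups)) {
    groups <- as.factor(groups)
    if (length(groups) != ncol(intensity)) {
      stopf("'groups' length must equal the number of samples")
    }
  }
  structure(list(intensity = intensity, probe_info = probe_info,
                 groups = groups),
            class = "probe_experiment")
}

#' @export
print.probe_experiment <- function(x, ...) {
  cat(sprintf(
    "<probe_experiment> %d probes (%d gene, %d control, %d background) x %d samples\n",
    nrow(x$intensity), sum(x$probe_info$type == "gene"),
    sum(x$probe_info$type == "control"),
    sum(x$probe_info$type == "background"), ncol(x$intensity)))
  invisible(x)
}

n_samples <- function(exp) ncol(exp$intensity)

# Centred two-level batch assignment balanced within each group, so the
# injected technical factor is orthogonal to the contrast of interest.
stratified_batch <- function(groups) {
  z <- numeric(length(groups))
  for (g in levels(groups)) {
    idx <- which(groups == g)
    z[idx] <- sample(rep(c(-0.5, 0.5), length.out = length(idx)))
  }
  z
}

# Pick genes to carry the injected group effect, preferring baselines at or
# above the median expression level; if the pool is too small, the highest
# baselines are used.
sample_de_genes <- function(mu, n_de) {
  if (n_de == 0L) return(integer())
  pool <- which(mu >= stats::median(mu))
  if (length(pool) < n_de) {
    pool <- order(mu, decreasing = TRUE)[seq_len(n_de)]
  }
  sample(pool, n_de)
}

#' Generate a synthetic probe-level experiment with known ground truth
#'
#' Simulates a two-group array series under the model described in
#' [synthetic_design()]. Besides the regular gene probes, each array carries
#' two housekeeping control transcripts ("hk1", a GAPDH analogue, and "hk2", a
#' beta-actin analogue) whose probes are labelled by their 5'-to-3' position
#' so that degradation shows up as an elevated 3'/5' intensity ratio, and a
#' block of background probes from which the optical background level is
#' estimated.
#'
#' Ground truth (true differential genes and directions, batch assignments,
#' and the injected failures) is returned alongside the data, never embedded
#' in it, so parameter-recovery tests can compare estimates to the truth.
#' Differential genes are drawn from the expressed half of the baseline
#' distribution: a transcript whose probes sit at the optical background
#' cannot carry a measurable fold change, so injecting effects there would
#' create ground truth the data do not contain.
#'
#' @param design A [synthetic_design()].
#' @param failures List of [qc_failure()] specifications (possibly empty).
#' @param n_background Number of background probes.
#' @param bg_level Mean additive background intensity (natural scale).
#' @return A list with elements `experiment` (a [probe_experiment()]) and
#'   `truth` (a list with `genes` — data frame of `gene`, `is_de`,
#'   `direction` —, `batch` — samples x factors matrix of centred batch
#'   indicators —, `failures`, and the `design`).
#' @export
generate_probe_experiment <- function(design, failures = list(),
                                      n_background = 200, bg_level = 50) {
  stopifnot(inherits(design, "synthetic_design"))
  if (inherits(failures, "qc_failure")) failures <- list(failures)
  ok <- vapply(failures, inherits, logical(1), what = "qc_failure")
  if (!all(ok)) stopf("'failures' must be a list of qc_failure objects")
  n_smp <- 2L * design$n_per_group
  bad_idx <- vapply(failures, function(f) f$sample, integer(1))
  if (length(bad_idx) && any(bad_idx > n_smp)) {
    stopf("failure sample index %d exceeds the number of samples (%d)",
          max(bad_idx), n_smp)
  }

  with_seed(design$seed, {
    G <- design$n_genes
    P <- design$probes_per_gene
    genes <- sprintf("G%05d", seq_len(G))
    groups <- factor(rep(c("group1", "group2"), each = design$n_per_group),
                     levels = c("group1", "group2"))

    mu <- stats::rnorm(G, mean = 8, sd = 1.5)       # gene baselines (log2)

    # true DE assignment: injected into expressed genes (baseline at or
    # above the median), since transcripts near the optical background
    # cannot carry a measurable fold change
    de_sign <- integer(G)
    de_idx <- sample_de_genes(mu, design$n_de_up + design$n_de_down)
    if (design$n_de_up > 0) de_sign[de_idx[seq_len(design$n_de_up)]] <- 1L
    if (design$n_de_down > 0) {
      de_sign[de_idx[design$n_de_up + seq_len(design$n_de_down)]] <- -1L
    }

    # batch factors: centred two-level assignments balanced within each
    # group (orthogonal to the contrast of interest), gene-specific load
    batch <- matrix(0, n_smp, 0)
    batch_load <- NULL
    if (design$n_batch_factors > 0) {
      batch <- vapply(seq_len(design$n_batch_factors), function(b) {
        stratified_batch(groups)
      }, numeric(n_smp))
      batch_load <- matrix(stats::rnorm(G * design$n_batch_factors,
                                        sd = design$batch_sd),
                           G, design$n_batch_factors)
    }

    affin <- stats::rnorm(G * P, mean = 0, sd = 0.7) # per-probe affinities

    # log2 signal for gene probes: gene x probe x sample flattened by probe row
    gene_of_probe <- rep(seq_len(G), each = P)
    probe_pos <- rep((seq_len(P) - 0.5) / P, times = G)  # 5' (0) -> 3' (1)
    base <- mu[gene_of_probe] + affin
    grp_eff <- ifelse(groups == "group1", 1, 0)
    l2 <- outer(base, rep(1, n_smp)) +
      outer(de_sign[gene_of_probe] * design$effect_log2fc, grp_eff)
    if (design$n_batch_factors > 0) {
      l2 <- l2 + batch_load[gene_of_probe, , drop = FALSE] %*% t(batch)
    }

    # housekeeping controls: 25 probes each (10 at the 5' end, 5 in the
    # middle, 10 at the 3' end) so the 3'/5' ratio of a clean array sits
    # tightly around 1
    hk_pos <- c(seq(0.02, 0.30, length.out = 10),
                seq(0.40, 0.60, length.out = 5),
                seq(0.70, 0.98, length.out = 10))
    hk_end <- rep(c("5prime", "middle", "3prime"), times = c(10, 5, 10))
    hk_l2 <- lapply(c(hk1 = 10, hk2 = 10.5), function(level) {
      outer(level + stats::rnorm(length(hk_pos), sd = 0.15), rep(1, n_smp))
    })

    # per-sample noise scale (inflated_noise multiplies it)
    noise_scale <- rep(1, n_smp)
    for (f in failures) {
      if (f$mode == "inflated_noise") {
        noise_scale[f$sample] <- noise_scale[f$sample] * f$severity
      }
    }
    add_noise <- function(m) {
      m + matrix(stats::rnorm(length(m), sd = design$noise_sd), nrow(m)) *
        rep(noise_scale, each = nrow(m))
    }
    l2 <- add_noise(l2)
    hk_l2 <- lapply(hk_l2, add_noise)

    # degradation: multiplicative 5'->3' gradient on the log2 scale
    for (f in failures) {
      if (f$mode == "degraded_3prime") {
        l2[, f$sample] <- l2[, f$sample] - f$severity * (1 - probe_pos)
        for (h in names(hk_l2)) {
          hk_l2[[h]][, f$sample] <- hk_l2[[h]][, f$sample] -
            f$severity * (1 - hk_pos)
        }
      }
    }

    signal <- 2^l2
    hk_signal <- lapply(hk_l2, function(m) 2^m)

    # loss of detectable signal: silence a fraction of genes in one sample
    for (f in failures) {
      if (f$mode == "low_percent_present") {
        frac <- min(0.9, 0.15 * f$severity)
        silenced <- sample.int(G, floor(frac * G))
        signal[gene_of_probe %in% silenced, f$sample] <- 0
      }
    }

    # additive optical background (shifted for high_background samples)
    bg_mean <- rep(bg_level, n_smp)
    for (f in failures) {
      if (f$mode == "high_background") {
        bg_mean[f$sample] <- bg_mean[f$sample] + 20 * f$severity
      }
    }
    rnorm_bg <- function(n_rows) {
      pmax(matrix(stats::rnorm(n_rows * n_smp, mean = rep(bg_mean, each = n_rows),
                               sd = 5), n_rows),
           1)
    }
    intensity <- rbind(signal + rnorm_bg(nrow(signal)),
                       do.call(rbind, lapply(hk_signal, function(m) {
                         m + rnorm_bg(nrow(m))
                       })),
                       rnorm_bg(n_background))

    # global mis-scaling multiplies the whole array
    for (f in failures) {
      if (f$mode == "bad_scale") {
        intensity[, f$sample] <- intensity[, f$sample] * 2^f$severity
      }
    }

    probe_info <- rbind(
      data.frame(probe_id = sprintf("%s_p%02d", genes[gene_of_probe],
                                    rep(seq_len(P), times = G)),
                 gene = genes[gene_of_probe], type = "gene", hk = NA_character_,
                 end = NA_character_, pos_frac = probe_pos,
                 stringsAsFactors = FALSE),
      data.frame(probe_id = c(sprintf("hk1_p%d", seq_along(hk_pos)),
                              sprintf("hk2_p%d", seq_along(hk_pos))),
                 gene = NA_character_, type = "control",
                 hk = rep(c("hk1", "hk2"), each = length(hk_pos)),
                 end = rep(hk_end, 2L), pos_frac = rep(hk_pos, 2L),
                 stringsAsFactors = FALSE),
      data.frame(probe_id = sprintf("bg_p%03d", seq_len(n_background)),
                 gene = NA_character_, type = "background",
                 hk = NA_character_, end = NA_character_,
                 pos_frac = NA_real_, stringsAsFactors = FALSE))
    rownames(intensity) <- probe_info$probe_id
    colnames(intensity) <- sprintf("S%02d", seq_len(n_smp))

    exp <- probe_experiment(intensity, probe_info, groups = groups)
    truth <- list(
      genes = data.frame(gene = genes, is_de = de_sign != 0L,
                         direction = c("down", "none", "up")[de_sign + 2L],
                         stringsAsFactors = FALSE),
      batch = batch, failures = failures, design = design)
    list(experiment = exp, truth = truth)
  })
}

#' Generate a gene-level expression matrix with known ground truth
#'
#' Convenience generator producing a pre-summarized log2 gene x sample matrix
#' under the same two-group model as [generate_probe_experiment()] but without
#' the probe layer: here `noise_sd` is the per-gene residual SD of the
#' summarized values. Useful for testing stages that consume gene-level input
#' (differential expression, batch correction) in isolation.
#'
#' @inheritParams generate_probe_experiment
#' @return A list with `expr` (log2 matrix, genes x samples), `groups`
#'   (factor), and `truth` (as in [generate_probe_experiment()]).
#' @export
generate_expression_matrix <- function(design) {
  stopifnot(inherits(design, "synthetic_design"))
  n_smp <- 2L * design$n_per_group
  with_seed(design$seed, {
    G <- design$n_genes
    genes <- sprintf("G%05d", seq_len(G))
    groups <- factor(rep(c("group1", "group2"), each = design$n_per_group),
                     levels = c("group1", "group2"))
    mu <- stats::rnorm(G, 8, 1.5)
    de_sign <- integer(G)
    de_idx <- sample_de_genes(mu, design$n_de_up + design$n_de_down)
    if (design$n_de_up > 0) de_sign[de_idx[seq_len(design$n_de_up)]] <- 1L
    if (design$n_de_down > 0) {
      de_sign[de_idx[design$n_de_up + seq_len(design$n_de_down)]] <- -1L
    }
    batch <- matrix(0, n_smp, 0)
    expr <- outer(mu, rep(1, n_smp)) +
      outer(de_sign * design$effect_log2fc,
            ifelse(groups == "group1", 1, 0))
    if (design$n_batch_factors > 0) {
      batch <- vapply(seq_len(design$n_batch_factors), function(b) {
        stratified_batch(groups)
      }, numeric(n_smp))
      load <- matrix(stats::rnorm(G * design$n_batch_factors,
                                  sd = design$batch_sd),
                     G, design$n_batch_factors)
      expr <- expr + load %*% t(batch)
    }
    expr <- expr + matrix(stats::rnorm(G * n_smp, sd = design$noise_sd), G)
    dimnames(expr) <- list(genes, sprintf("S%02d", seq_len(n_smp)))
    list(expr = expr, groups = groups,
         truth = list(genes = data.frame(gene = genes, is_de = de_sign != 0L,
                                         direction = c("down", "none",
                                                       "up")[de_sign + 2L],
                                         stringsAsFactors = FALSE),
                      batch = batch, failures = list(), design = design))
  })
}

#' Generate a synthetic differential-expression table
#'
#' Shortcut fixture for testing gene-set extraction and consensus logic
#' without running a full differential-expression analysis: produces a table
#' in which exactly `n_sig_up` genes have adjusted p < 0.05 with positive
#' log2 fold change and exactly `n_sig_down` with negative, with distinct B
#' scores so that ranking is unambiguous.
#'
#' @param n_genes Number of genes.
#' @param n_sig_up,n_sig_down Numbers of significant up-/downregulated genes;
#'   their sum must not exceed `n_genes`.
#' @param seed Integer seed.
#' @return A data frame with columns `gene`, `logFC`, `AveExpr`, `t`,
#'   `P.Value`, `adj.P.Val`, `B`, `filtered` (the differential-expression
#'   result layout used throughout the package).
#' @export
generate_de_table <- function(n_genes, n_sig_up, n_sig_down, seed = 1) {
  if (!is_count(n_genes)) stopf("'n_genes' must be a positive integer")
  for (nm in c("n_sig_up", "n_sig_down")) {
    v <- get(nm)
    if (!(is.numeric(v) && length(v) == 1L && v >= 0 && v == floor(v))) {
      stopf("'%s' must be a non-negative integer", nm)
    }
  }
  if (n_sig_up + n_sig_down > n_genes) {
    stopf("n_sig_up + n_sig_down must not exceed n_genes")
  }
  with_seed(seed, {
    genes <- sprintf("G%05d", seq_len(n_genes))
    n_sig <- n_sig_up + n_sig_down
    sig_idx <- sample.int(n_genes, n_sig)
    sign <- numeric(n_genes)
    if (n_sig_up > 0) sign[sig_idx[seq_len(n_sig_up)]] <- 1
    if (n_sig_down > 0) sign[sig_idx[n_sig_up + seq_len(n_sig_down)]] <- -1
    adj <- stats::runif(n_genes, 0.05, 1)
    adj[sig_idx] <- stats::runif(n_sig, 1e-8, 0.049)
    raw <- adj * stats::runif(n_genes, 0.3, 1)
    lfc <- stats::rnorm(n_genes, 0, 0.2)
    lfc[sign != 0] <- sign[sign != 0] * stats::runif(n_sig, 0.5, 3)
    df <- 6
    tt <- sign(lfc) * stats::qt(1 - raw / 2, df = df)
    # distinct B scores, monotone decreasing in raw p
    b <- -log(raw)
    b <- b + stats::runif(n_genes, 0, 1e-9)
    data.frame(gene = genes, logFC = lfc,
               AveExpr = stats::rnorm(n_genes, 8, 1.5), t = tt,
               P.Value = raw, adj.P.Val = adj, B = b, filtered = FALSE,
               stringsAsFactors = FALSE)
  })
}
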