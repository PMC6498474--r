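#' Pipeline configuration
#'
#' Bundles every tunable of the build pipeline in one object; each threshold
#' defaults to the standard value used throughout the package (QC thresholds
#' from [qc_thresholds()], inclusion rules from [de_config()], consensus
#' rules from [consensus_config()], surrogate-variable settings, enrichment
#' settings, and the global seed recorded in the output manifest).
#'
#' @param seed Global integer seed; every stochastic stage derives its seed
#'   from it.
#' @param qc A [qc_thresholds()].
#' @param de A [de_config()].
#' @param consensus A [consensus_config()].
#' @param batch List with `max_sv` and `n_perm` for [estimate_surrogates()];
#'   set `max_sv = 0` to disable batch correction.
#' @param enrichment List with `min_set_size`, `n_random` and `ignore_case`
#'   for [hypergeometric_enrich()].
#' @param run_qc Apply the QC battery and discard failing samples.
#' @param strict_consensus Strict direction consistency for
#'   [consensus_build()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1, qc = qc_thresholds(),
                            de = de_config(),
                            consensus = consensus_config(),
                            batch = list(max_sv = 2, n_perm = 20),
                            enrichment = list(min_set_size = 1,
                                              n_random = 100,
                                              ignore_case = FALSE),
                            run_qc = TRUE, strict_consensus = TRUE) {
  stopifnot(inherits(qc, "qc_thresholds"), inherits(de, "de_config"),
            inherits(consensus, "consensus_config"))
  if (!is.numeric(seed) || length(seed) != 1L) {
    stopf("'seed' must be a single integer")
  }
  structure(list(seed = as.integer(seed), qc = qc, de = de,
                 consensus = consensus, batch = batch,
                 enrichment = enrichment, run_qc = isTRUE(run_qc),
                 strict_consensus = isTRUE(strict_consensus)),
            class = "pipeline_config")
}

#' Read a pipeline configuration from a YAML file
#'
#' Every key is optional and overrides the corresponding default of
#' [pipeline_config()]; recognized top-level keys are `seed`, `qc`, `de`,
#' `consensus`, `batch`, `enrichment`, `run_qc`, `strict_consensus`, with
#' the nested keys named as the constructor arguments.
#'
#' @param path Path to a YAML file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE)) {
    stopf("reading YAML configuration requires the 'yaml' package")
  }
  raw <- yaml::read_yaml(path)
  args <- list()
  if (!is.null(raw$seed)) args$seed <- raw$seed
  if (!is.null(raw$qc)) args$qc <- do.call(qc_thresholds, raw$qc)
  if (!is.null(raw$de)) args$de <- do.call(de_config, raw$de)
  if (!is.null(raw$consensus)) {
    args$consensus <- do.call(consensus_config, raw$consensus)
  }
  if (!is.null(raw$batch)) args$batch <- raw$batch
  if (!is.null(raw$enrichment)) args$enrichment <- raw$enrichment
  if (!is.null(raw$run_qc)) args$run_qc <- raw$run_qc
  if (!is.null(raw$strict_consensus)) {
    args$strict_consensus <- raw$strict_consensus
  }
  do.call(pipeline_config, args)
}

run_stage <- function(stage, entity, expr) {
  tryCatch(expr, error = function(e) {
    stopf("stage '%s' failed for %s: %s", stage, entity,
          conditionMessage(e))
  })
}

#' Run the full build pipeline
#'
#' Executes, per comparison: quality control with sample discarding
#' ([qc_report()]), preprocessing to gene level
#' ([preprocess_experiment()]), surrogate-variable estimation and removal
#' ([estimate_surrogates()]), differential expression ([run_de()]) and
#' gene-set extraction ([extract_gene_sets()]); then assembles the
#' direction-split collection, optionally builds consensus sets for tagged
#' comparison groups, and writes all outputs plus a manifest to `out_dir`:
#'
#' * `qc_report.tsv` — all metrics, flags and verdicts per sample;
#' * `de/de_<id>.tsv` — one differential-expression table per comparison;
#' * `collection.gmt` — the 2-sets-per-comparison collection;
#' * `surrogates_<id>.tsv` — surrogate values, when any were removed;
#' * `consensus.gmt` and `support_<tag>.tsv` — when tags are present;
#' * `manifest.json` — seed, thresholds and per-stage counts;
#' * `pipeline.log` — the stage-granularity log (also emitted as messages).
#'
#' Any stage error aborts with the stage name and the offending comparison.
#' Outputs are deterministic: rerunning with the same inputs and seed gives
#' byte-identical files.
#'
#' @param experiments List of comparisons; each element is a list with
#'   `experiment` (a [probe_experiment()] whose `groups` factor has two
#'   levels), `meta` (a [comparison_meta()]), and optionally `tag` (a
#'   consensus comparison tag).
#' @param out_dir Output directory (created if missing).
#' @param config A [pipeline_config()].
#' @return Invisibly, a list with `collection`, `consensus`, `manifest`,
#'   `qc`, `de` (list of DE tables).
#' @export
run_build <- function(experiments, out_dir, config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  dir.create(file.path(out_dir, "de"), showWarnings = FALSE)
  log_lines <- character()
  log_msg <- function(fmt, ...) {
    line <- sprintf(fmt, ...)
    message(line)
    log_lines <<- c(log_lines, line)
  }

  ids <- vapply(experiments, function(e) e$meta$mgs_id, integer(1))
  if (anyDuplicated(ids)) {
    stopf("duplicate comparison id(s): %s",
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  }

  qc_all <- list()
  de_tables <- list()
  sets <- list()
  counts <- list()
  for (i in seq_along(experiments)) {
    cmp <- experiments[[i]]
    meta <- cmp$meta
    entity <- sprintf("comparison %d (id %d)", i, meta$mgs_id)
    exp <- cmp$experiment
    groups <- exp$groups
    if (is.null(groups)) {
      stopf("stage 'qc' failed for %s: experiment has no group assignments",
            entity)
    }
    n_total <- n_samples(exp)

    discarded <- character()
    if (config$run_qc) {
      rep <- run_stage("qc", entity, qc_report(exp, config$qc))
      rep$comparison_id <- meta$mgs_id
      qc_all[[i]] <- rep
      failed <- rep$verdict == "fail"
      discarded <- rep$sample[failed]
      if (any(failed)) {
        keep <- !failed
        exp$intensity <- exp$intensity[, keep, drop = FALSE]
        groups <- droplevels(groups[keep])
        exp$groups <- groups
      }
      if (nlevels(groups) < 2L || any(table(groups) < 2L)) {
        stopf("stage 'qc' failed for %s: fewer than 2 samples per group remain after discarding %d sample(s)",
              entity, sum(failed))
      }
      log_msg("[qc] %s: %d/%d sample(s) discarded (%s)", entity,
              length(discarded), n_total,
              if (length(discarded)) paste(discarded, collapse = ",")
              else "none")
    }

    expr <- run_stage("preprocess", entity, preprocess_experiment(exp))
    log_msg("[preprocess] %s: %d gene(s) x %d sample(s)", entity,
            nrow(expr), ncol(expr))

    n_sv <- 0L
    if (config$batch$max_sv > 0) {
      sv <- run_stage("batch", entity,
                      estimate_surrogates(expr, groups,
                                          max_sv = config$batch$max_sv,
                                          n_perm = config$batch$n_perm,
                                          seed = config$seed + i))
      expr <- sv$corrected
      n_sv <- sv$n_sv
      if (n_sv > 0) {
        write_tsv(data.frame(sample = rownames(sv$surrogates),
                             sv$surrogates, check.names = FALSE),
                  file.path(out_dir,
                            sprintf("surrogates_%d.tsv", meta$mgs_id)))
      }
      log_msg("[batch] %s: %d surrogate variable(s) removed", entity, n_sv)
    }

    de <- run_stage("dge", entity,
                    run_de(expr, groups, config$de, df_lost = n_sv))
    de_tables[[i]] <- de
    n_filtered <- sum(de$filtered)
    write_de_table(de, file.path(out_dir, "de",
                                 sprintf("de_%d.tsv", meta$mgs_id)))
    log_msg("[dge] %s: %d gene(s) tested, %d removed by low-expression filter, %d significant",
            entity, sum(!de$filtered), n_filtered,
            sum(de$adj.P.Val < config$de$fdr_threshold, na.rm = TRUE))

    pair <- run_stage("extract", entity,
                      extract_gene_sets(de, meta, config$de))
    sets[[2L * i - 1L]] <- pair$up
    sets[[2L * i]] <- pair$down
    log_msg("[extract] %s: up %d gene(s), down %d gene(s)", entity,
            length(pair$up$genes), length(pair$down$genes))

    counts[[i]] <- list(comparison_id = meta$mgs_id,
                        samples_total = n_total,
                        samples_discarded = length(discarded),
                        genes_summarized = nrow(expr),
                        genes_filtered = n_filtered,
                        surrogate_variables = n_sv,
                        up_set_size = length(pair$up$genes),
                        down_set_size = length(pair$down$genes))
  }

  collection <- gene_set_collection(sets, label = "collection")
  write_gmt(collection, file.path(out_dir, "collection.gmt"))
  if (length(qc_all)) {
    write_tsv(do.call(rbind, qc_all), file.path(out_dir, "qc_report.tsv"))
  }

  consensus <- NULL
  tags <- vapply(experiments, function(e) e$tag %||% NA_character_,
                 character(1))
  if (any(!is.na(tags))) {
    groups_by_tag <- lapply(split(which(!is.na(tags)), tags[!is.na(tags)]),
                            function(idx) {
                              lapply(idx, function(i) {
                                list(up = sets[[2L * i - 1L]],
                                     down = sets[[2L * i]])
                              })
                            })
    consensus <- run_stage("consensus", "tagged comparison groups",
                           consensus_collection(groups_by_tag,
                                                config$consensus,
                                                strict = config$strict_consensus))
    write_gmt(consensus, file.path(out_dir, "consensus.gmt"))
    for (tag in names(groups_by_tag)) {
      write_tsv(consensus_support(groups_by_tag[[tag]]),
                file.path(out_dir, sprintf("support_%s.tsv", tag)))
    }
    log_msg("[consensus] %d tagged group(s) -> %d consensus set(s)",
            length(groups_by_tag), length(consensus))
  }

  manifest <- list(
    seed = config$seed,
    thresholds = list(qc = unclass(config$qc), de = unclass(config$de),
                      consensus = unclass(config$consensus),
                      batch = config$batch),
    n_comparisons = length(experiments),
    n_sets = length(collection),
    n_empty_sets = sum(vapply(collection, length, integer(1)) == 0L),
    n_consensus_sets = if (is.null(consensus)) 0L else length(consensus),
    samples_total = sum(vapply(counts, `[[`, numeric(1), "samples_total")),
    samples_discarded = sum(vapply(counts, `[[`, numeric(1),
                                   "samples_discarded")),
    comparisons = counts)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  writeLines(log_lines, file.path(out_dir, "pipeline.log"))
  invisible(list(collection = collection, consensus = consensus,
                 manifest = manifest, qc = qc_all, de = de_tables))
}

#' Run enrichment of a query gene list against a collection
#'
#' Reads the collection (GMT path or [gene_set_collection()]), the query and
#' the universe (newline-delimited file paths or character vectors), runs
#' [hypergeometric_enrich()], and writes the result as a TSV sorted by
#' adjusted p value. A header row is always written, even when no set is
#' significant; success of the call reflects completion, not significance.
#'
#' @param collection GMT path or [gene_set_collection()].
#' @param query Path to a newline-delimited gene list, or character vector.
#' @param universe Path or character vector of background genes.
#' @param out_file Output TSV path.
#' @param config A [pipeline_config()] (its `enrichment` and `seed` entries
#'   are used).
#' @return The enrichment data frame, invisibly.
#' @export
run_enrich <- function(collection, query, universe, out_file,
                       config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  if (is.character(collection) && length(collection) == 1L) {
    collection <- read_gmt(collection)
  }
  if (is.character(query) && length(query) == 1L && file.exists(query)) {
    query <- read_gene_list(query)
  }
  if (is.character(universe) && length(universe) == 1L &&
      file.exists(universe)) {
    universe <- read_gene_list(universe)
  }
  res <- hypergeometric_enrich(
    query, collection, universe,
    min_set_size = config$enrichment$min_set_size %||% 1,
    ignore_case = isTRUE(config$enrichment$ignore_case),
    n_random = config$enrichment$n_random %||% 100,
    seed = config$seed)
  write_tsv(res, out_file)
  invisible(res)
}
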