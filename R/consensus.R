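#' Consensus-construction configuration
#'
#' Rules for building consensus sets across studies of the same comparison:
#' support thresholds (fractions of contributing studies that must share a
#' gene), the three direction categories (up, down, same), and the
#' eligibility floor — a comparison qualifies only if it has at least
#' `min_sets_per_comparison` gene sets with at least `min_sets_per_direction`
#' in each direction.
#'
#' @param support_thresholds Numeric vector of thresholds in (0, 1\], sorted
#'   ascending (default 0.30, 0.50, 0.70).
#' @param min_sets_per_comparison Minimum total gene sets per comparison.
#' @param min_sets_per_direction Minimum sets per direction.
#' @return An object of class `consensus_config`.
#' @export
consensus_config <- function(support_thresholds = c(0.30, 0.50, 0.70),
                             min_sets_per_comparison = 8,
                             min_sets_per_direction = 4) {
  if (!is.numeric(support_thresholds) || !length(support_thresholds) ||
      any(support_thresholds <= 0 | support_thresholds > 1)) {
    stopf("'support_thresholds' must lie in (0, 1]")
  }
  if (is.unsorted(support_thresholds, strictly = TRUE)) {
    stopf("'support_thresholds' must be sorted strictly ascending")
  }
  if (!is_count(min_sets_per_comparison) || !is_count(min_sets_per_direction)) {
    stopf("eligibility minima must be positive integers")
  }
  structure(list(support_thresholds = support_thresholds,
                 min_sets_per_comparison = as.integer(min_sets_per_comparison),
                 min_sets_per_direction = as.integer(min_sets_per_direction)),
            class = "consensus_config")
}

consensus_categories <- c("up", "down", "same")

#' Extract direction-split gene sets from a differential-expression result
#'
#' Candidate genes are those with adjusted p below the FDR threshold; they
#' are ranked by B score descending (ties broken by smaller raw p, then by
#' gene identifier), the top `max_genes_per_set` are kept, and the kept genes
#' are split by the sign of the log2 fold change into the up set (higher in
#' group 1) and the down set. Both sets are always returned, possibly empty —
#' an empty set records that a comparison yielded nothing significant and is
#' retained in the collection. A candidate with exactly zero fold change
#' belongs to neither direction and is dropped with a message.
#'
#' @param de Differential-expression data frame (as from
#'   [moderated_t_test()] or [generate_de_table()]).
#' @param meta A [comparison_meta()] used to name the sets.
#' @param config A [de_config()].
#' @return A list with elements `up` and `down`, each a [gene_set()].
#' @export
extract_gene_sets <- function(de, meta, config = de_config()) {
  stopifnot(is.data.frame(de), inherits(meta, "comparison_meta"),
            inherits(config, "de_config"))
  need <- c("gene", "logFC", "P.Value", "adj.P.Val", "B")
  miss <- setdiff(need, names(de))
  if (length(miss)) {
    stopf("DE result is missing column(s): %s", paste(miss, collapse = ", "))
  }
  cand <- de[!is.na(de$adj.P.Val) & de$adj.P.Val < config$fdr_threshold, ,
             drop = FALSE]
  cand <- cand[order(-cand$B, cand$P.Value, cand$gene), , drop = FALSE]
  kept <- utils::head(cand, config$max_genes_per_set)
  zero <- kept$logFC == 0
  if (any(zero)) {
    message(sprintf(
      "extract_gene_sets: %d significant gene(s) with zero log2 fold change assigned to neither direction",
      sum(zero)))
    kept <- kept[!zero, , drop = FALSE]
  }
  list(up = gene_set(build_set_name(meta, "up"), meta$source_id,
                     kept$gene[kept$logFC > 0]),
       down = gene_set(build_set_name(meta, "down"), meta$source_id,
                       kept$gene[kept$logFC < 0]))
}

#' Build a gene-set collection from many comparisons
#'
#' Emits exactly two gene sets per comparison (up before down), in input
#' order, so a collection built from `n` comparisons always has `2 * n` sets
#' — empty sets included. Comparison IDs must be unique.
#'
#' @param comparisons List of comparisons, each a list with elements `de` (a
#'   differential-expression data frame) and `meta` (a [comparison_meta()]).
#' @param config A [de_config()].
#' @param label Optional collection label.
#' @return A [gene_set_collection()] of size `2 * length(comparisons)`.
#' @export
build_collection <- function(comparisons, config = de_config(),
                             label = NULL) {
  ids <- vapply(comparisons, function(cmp) cmp$meta$mgs_id, integer(1))
  dup <- unique(ids[duplicated(ids)])
  if (length(dup)) {
    stopf("duplicate comparison id(s): %s", paste(dup, collapse = ", "))
  }
  sets <- vector("list", 2L * length(comparisons))
  for (i in seq_along(comparisons)) {
    pair <- extract_gene_sets(comparisons[[i]]$de, comparisons[[i]]$meta,
                              config)
    sets[[2L * i - 1L]] <- pair$up
    sets[[2L * i]] <- pair$down
  }
  gene_set_collection(sets, label = label)
}

#' Per-gene support counts across the studies of one comparison
#'
#' For every gene appearing in any contributing set, counts the number of
#' studies whose up set contains it (`U`), the number whose down set contains
#' it (`D`), and records the study denominator `k` (the number of studies
#' contributing at least one set — an empty set still counts as a
#' contributing study that found nothing).
#'
#' @param studies List of studies, each a list with elements `up` and/or
#'   `down` holding [gene_set()] objects (either may be `NULL`).
#' @return A data frame with columns `gene`, `U`, `D`, `k`, sorted by gene.
#' @export
consensus_support <- function(studies) {
  has_any <- vapply(studies, function(s) {
    !is.null(s$up) || !is.null(s$down)
  }, logical(1))
  k <- sum(has_any)
  up_genes <- unlist(lapply(studies, function(s) {
    if (is.null(s$up)) character() else unique(s$up$genes)
  }))
  down_genes <- unlist(lapply(studies, function(s) {
    if (is.null(s$down)) character() else unique(s$down$genes)
  }))
  genes <- sort(unique(c(up_genes, down_genes)))
  U <- table(factor(up_genes, levels = genes))
  D <- table(factor(down_genes, levels = genes))
  data.frame(gene = genes, U = as.integer(U), D = as.integer(D), k = k,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Build consensus sets for one comparison across studies
#'
#' A comparison is eligible if it carries at least
#' `min_sets_per_comparison` gene sets with at least
#' `min_sets_per_direction` per direction; ineligible comparisons yield an
#' empty result with a message stating the reason. For an eligible comparison
#' with `k` contributing studies, let `U(g)` and `D(g)` be the numbers of
#' studies whose up and down sets contain gene `g`. For each support
#' threshold `t`:
#'
#' * up-consensus: genes with `U(g)/k >= t` and `D(g) = 0`;
#' * down-consensus: genes with `D(g)/k >= t` and `U(g) = 0`;
#' * same-consensus: genes with `(U(g)+D(g))/k >= t` and `min(U, D) = 0`
#'   (dysregulated, in a consistent direction).
#'
#' Direction consistency is strict by default: a gene appearing in any
#' opposing-direction set is excluded from all three categories ("consistent"
#' means zero tolerance). With `strict = FALSE` the zero-opposition
#' requirement is relaxed to a majority rule (`U > D` for up, `D > U` for
#' down, no consistency condition for same). Support comparisons use exact
#' integer arithmetic (`100 * count >= percent * k`), so thresholds of
#' exactly 30/50/70% have no floating-point edge cases. The study count `k`,
#' not the set count `2k`, is the denominator. Three categories crossed with
#' three thresholds give 9 consensus sets per eligible comparison; within a
#' category the sets nest (higher thresholds are subsets of lower ones).
#'
#' @param studies List of studies as in [consensus_support()].
#' @param tag Comparison tag naming the tissue/contrast, e.g.
#'   `"HumanSkelMusc_DMD_v_Healthy"`.
#' @param config A [consensus_config()].
#' @param strict Logical; strict direction consistency (default `TRUE`).
#' @return A list of `consensus_set` objects (also valid [gene_set()]s, so a
#'   result can be wrapped in a [gene_set_collection()] and written as GMT);
#'   empty if the comparison is ineligible. Each element carries `tag`,
#'   `category`, `threshold`, `genes` and the study count `k`; its `info`
#'   field encodes the same for GMT round-tripping.
#' @export
consensus_build <- function(studies, tag, config = consensus_config(),
                            strict = TRUE) {
  stopifnot(inherits(config, "consensus_config"))
  n_up <- sum(vapply(studies, function(s) !is.null(s$up), logical(1)))
  n_down <- sum(vapply(studies, function(s) !is.null(s$down), logical(1)))
  n_sets <- n_up + n_down
  if (n_sets < config$min_sets_per_comparison ||
      min(n_up, n_down) < config$min_sets_per_direction) {
    message(sprintf(
      "consensus '%s' skipped: %d set(s) (%d up, %d down); need >= %d with >= %d per direction",
      tag, n_sets, n_up, n_down, config$min_sets_per_comparison,
      config$min_sets_per_direction))
    return(list())
  }
  if (n_up != n_down) {
    warnf("consensus '%s': unpaired direction counts (%d up, %d down); k counts studies contributing at least one set",
          tag, n_up, n_down)
  }
  sup <- consensus_support(studies)
  k <- sum(vapply(studies, function(s) {
    !is.null(s$up) || !is.null(s$down)
  }, logical(1)))
  out <- list()
  for (threshold in config$support_thresholds) {
    pct <- round(threshold * 100)
    meets <- function(count) 100L * count >= pct * k
    member <- list(
      up = if (strict) meets(sup$U) & sup$D == 0L
           else meets(sup$U) & sup$U > sup$D,
      down = if (strict) meets(sup$D) & sup$U == 0L
             else meets(sup$D) & sup$D > sup$U,
      same = if (strict) meets(sup$U + sup$D) & pmin(sup$U, sup$D) == 0L
             else meets(sup$U + sup$D))
    for (category in consensus_categories) {
      sel <- member[[category]]
      support <- switch(category, up = sup$U, down = sup$D,
                        same = sup$U + sup$D)
      ord <- order(-support[sel], sup$gene[sel])
      genes <- sup$gene[sel][ord]
      nm <- consensus_name(tag, category, threshold)
      cs <- gene_set(nm,
                     sprintf("tag=%s;category=%s;threshold=%d;k=%d",
                             tag, category, pct, k),
                     genes)
      cs$tag <- tag
      cs$category <- category
      cs$threshold <- threshold
      cs$k <- k
      class(cs) <- c("consensus_set", class(cs))
      out[[nm]] <- cs
    }
  }
  out
}

#' Build consensus sets for several tagged comparisons
#'
#' Applies [consensus_build()] to each element of a named list of comparison
#' groups and returns all emitted consensus sets as one
#' [gene_set_collection()] (9 sets per eligible comparison).
#'
#' @param groups Named list; each element is a `studies` list as accepted by
#'   [consensus_build()], named by its comparison tag.
#' @param config A [consensus_config()].
#' @param strict Passed to [consensus_build()].
#' @return A [gene_set_collection()] of consensus sets.
#' @export
consensus_collection <- function(groups, config = consensus_config(),
                                 strict = TRUE) {
  if (is.null(names(groups)) || any(!nzchar(names(groups)))) {
    stopf("'groups' must be a named list (names are the comparison tags)")
  }
  sets <- unlist(lapply(names(groups), function(tag) {
    consensus_build(groups[[tag]], tag, config, strict = strict)
  }), recursive = FALSE)
  gene_set_collection(unname(sets), label = "consensus")
}
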