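# Plain-text (TSV) interchange for every container: probe experiments,
# expression matrices, DE tables, QC reports, gene lists. All files are
# tab-separated UTF-8 with a header row.

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

read_tsv <- function(path) {
  utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE, fileEncoding = "UTF-8")
}

#' Write a probe-level experiment as tab-separated text
#'
#' Produces three files under `dir`: `<prefix>_intensity.tsv` (probe rows,
#' sample columns), `<prefix>_probes.tsv` (the probe annotation table) and
#' `<prefix>_samples.tsv` (sample labels and group assignments).
#'
#' @param exp A [probe_experiment()].
#' @param dir Output directory (created if missing).
#' @param prefix File-name prefix.
#' @return The three file paths, invisibly.
#' @export
write_probe_experiment <- function(exp, dir, prefix = "experiment") {
  stopifnot(inherits(exp, "probe_experiment"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- file.path(dir, paste0(prefix, c("_intensity.tsv", "_probes.tsv",
                                           "_samples.tsv")))
  write_tsv(data.frame(probe_id = rownames(exp$intensity), exp$intensity,
                       check.names = FALSE), paths[1])
  write_tsv(exp$probe_info, paths[2])
  write_tsv(data.frame(sample = colnames(exp$intensity),
                       group = if (is.null(exp$groups)) NA else
                         as.character(exp$groups)), paths[3])
  invisible(paths)
}

#' Read a probe-level experiment written by [write_probe_experiment()]
#'
#' @param dir Directory holding the three TSV files.
#' @param prefix File-name prefix used when writing.
#' @return A [probe_experiment()].
#' @export
read_probe_experiment <- function(dir, prefix = "experiment") {
  inten <- read_tsv(file.path(dir, paste0(prefix, "_intensity.tsv")))
  probes <- read_tsv(file.path(dir, paste0(prefix, "_probes.tsv")))
  samples <- read_tsv(file.path(dir, paste0(prefix, "_samples.tsv")))
  m <- as.matrix(inten[, -1, drop = FALSE])
  rownames(m) <- inten$probe_id
  groups <- if (all(is.na(samples$group))) NULL else factor(samples$group)
  probes$gene <- as.character(probes$gene)
  probes$hk <- as.character(probes$hk)
  probes$end <- as.character(probes$end)
  probe_experiment(m, probes, groups = groups)
}

#' Write a gene-level expression matrix as TSV
#'
#' @param expr Gene x sample matrix with gene row names.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_expression_matrix <- function(expr, path) {
  write_tsv(data.frame(gene = rownames(expr), expr, check.names = FALSE),
            path)
}

#' Read a gene-level expression matrix written by
#' [write_expression_matrix()]
#'
#' @param path Input path.
#' @return Gene x sample numeric matrix.
#' @export
read_expression_matrix <- function(path) {
  df <- read_tsv(path)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df$gene
  m
}

#' Write a differential-expression table as TSV
#'
#' Columns: `gene`, `logFC`, `AveExpr`, `t`, `P.Value`, `adj.P.Val`, `B`
#' (plus any extras present, e.g. `df.total`, `filtered`).
#'
#' @param de Differential-expression data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_de_table <- function(de, path) {
  lead <- intersect(c("gene", "logFC", "AveExpr", "t", "P.Value",
                      "adj.P.Val", "B"), names(de))
  write_tsv(de[, c(lead, setdiff(names(de), lead)), drop = FALSE], path)
}

#' Read a newline-delimited gene list
#'
#' @param path Text file with one gene symbol per line; blank lines and
#'   surrounding whitespace are dropped.
#' @return Character vector of gene symbols.
#' @export
read_gene_list <- function(path) {
  x <- trimws(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x)]
}
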