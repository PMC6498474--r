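#' Create a gene set
#'
#' A gene set is a named, ordered list of unique gene symbols together with an
#' information field recording its provenance (typically the accession of the
#' series the set was derived from). Empty gene lists are legal and are
#' preserved through all I/O: an empty set records that a comparison yielded
#' no significant genes, which is itself informative (e.g. during consensus
#' construction, where an empty set counts as a contributing study that found
#' nothing).
#'
#' @param name Set name. Must be non-empty and contain no tab characters.
#' @param info Free-text provenance field (may be empty).
#' @param genes Character vector of gene symbols. Duplicates are removed,
#'   keeping the first occurrence; empty strings are dropped. Symbols are
#'   stored verbatim (case preserved).
#' @return An object of class `gene_set` with elements `name`, `info`,
#'   `genes`.
#' @export
#' @examples
#' gene_set("up_in_mdx_v_WT___mouse_8wk_gastroc_42", "GSE123",
#'          c("Myod1", "Des"))
gene_set <- function(name, info = "", genes = character()) {
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    stopf("gene set 'name' must be a single non-empty string")
  }
  if (grepl("\t", name, fixed = TRUE)) {
    stopf("gene set name must not contain tab characters: %s", name)
  }
  if (!is.character(info) || length(info) != 1L) {
    stopf("gene set 'info' must be a single string")
  }
  genes <- as.character(genes)
  genes <- genes[nzchar(genes) & !is.na(genes)]
  genes <- genes[!duplicated(genes)]
  structure(list(name = name, info = info, genes = genes),
            class = "gene_set")
}

#' @export
print.gene_set <- function(x, ...) {
  cat(sprintf("<gene_set> %s [%s]: %d gene(s)\n", x$name, x$info,
              length(x$genes)))
  if (length(x$genes)) {
    shown <- utils::head(x$genes, 10L)
    cat("  ", paste(shown, collapse = ", "),
        if (length(x$genes) > 10L) ", ..." else "", "\n", sep = "")
  }
  invisible(x)
}

#' @export
length.gene_set <- function(x) length(x$genes)

#' Create a collection of gene sets
#'
#' @param sets List of [gene_set()] objects. Set names must be unique within
#'   the collection; input order is preserved.
#' @param label Optional collection label.
#' @return An object of class `gene_set_collection`: a list of gene sets with
#'   a `label` attribute.
#' @export
gene_set_collection <- function(sets = list(), label = NULL) {
  if (inherits(sets, "gene_set")) sets <- list(sets)
  ok <- vapply(sets, inherits, logical(1), what = "gene_set")
  if (!all(ok)) stopf("all elements of 'sets' must be gene_set objects")
  nm <- vapply(sets, function(s) s$name, character(1))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stopf("duplicate gene set name(s) in collection: %s",
          paste(dup, collapse = ", "))
  }
  names(sets) <- nm
  structure(sets, label = label, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  lab <- attr(x, "label")
  cat(sprintf("<gene_set_collection>%s %d set(s), %d empty\n",
              if (is.null(lab)) "" else paste0(" '", lab, "'"),
              length(x), sum(vapply(x, length, integer(1)) == 0L)))
  invisible(x)
}

#' @export
`[.gene_set_collection` <- function(x, i) {
  gene_set_collection(unclass(x)[i], label = attr(x, "label"))
}

#' Read a GMT file
#'
#' Parses the tab-delimited MSigDB-style gene-set format: one set per line,
#' with the set name in field 1, an information/provenance field in field 2,
#' and member genes in the remaining fields. Blank gene fields are dropped and
#' duplicate symbols within a line are removed keeping the first occurrence.
#' Lines with fewer than two fields (including the info field) are a parse
#' error. Input is read as UTF-8; CRLF line endings are normalized.
#'
#' @param path Path to a GMT file, or a connection.
#' @param label Optional label for the returned collection (defaults to the
#'   file name).
#' @return A [gene_set_collection()].
#' @seealso [write_gmt()]
#' @export
read_gmt <- function(path, label = NULL) {
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- nzchar(trimws(lines))
  line_no <- which(keep)
  lines <- lines[keep]
  if (is.null(label) && is.character(path)) label <- basename(path)
  sets <- vector("list", length(lines))
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 2L) {
      stopf("GMT parse error at line %d: expected at least 2 tab-delimited fields (name, info), got %d",
            line_no[i], length(fields))
    }
    sets[[i]] <- gene_set(fields[1L], fields[2L],
                          fields[-(1:2)])
  }
  gene_set_collection(sets, label = label)
}

#' Write a GMT file
#'
#' Inverse of [read_gmt()]: `read_gmt(write_gmt(x, path))` reproduces the
#' collection exactly, including set order, gene order, and empty sets (an
#' empty set is written as `name<TAB>info` with no gene fields). Output uses
#' UTF-8 and `\n` line endings.
#'
#' @param collection A [gene_set_collection()].
#' @param path Output path or connection.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(collection, path) {
  stopifnot(inherits(collection, "gene_set_collection"))
  lines <- vapply(collection, function(s) {
    paste(c(s$name, s$info, s$genes), collapse = "\t")
  }, character(1))
  writeLines(lines, path, useBytes = FALSE)
  invisible(path)
}

#' Merge gene-set collections
#'
#' Concatenates collections in the given order. Set names must be unique
#' across all inputs; the merged size is the sum of the input sizes. This is
#' how independently derived sub-collections (e.g. the main comparison-derived
#' sets, legacy meta-analysis sets, and sets harvested from public resources)
#' are combined into one distributable collection.
#'
#' @param collections List of [gene_set_collection()] objects.
#' @param label Optional label for the merged collection.
#' @return A [gene_set_collection()] of size `sum(lengths(collections))`.
#' @export
merge_collections <- function(collections, label = NULL) {
  if (inherits(collections, "gene_set_collection")) {
    collections <- list(collections)
  }
  ok <- vapply(collections, inherits, logical(1),
               what = "gene_set_collection")
  if (!all(ok)) stopf("all inputs must be gene_set_collection objects")
  all_sets <- unlist(lapply(collections, unclass), recursive = FALSE)
  nm <- vapply(all_sets, function(s) s$name, character(1))
  dup <- unique(nm[duplicated(nm)])
  if (length(dup)) {
    stopf("cannot merge: set name(s) present in more than one collection: %s",
          paste(dup, collapse = ", "))
  }
  gene_set_collection(all_sets, label = label)
}
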