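#' Describe a two-group comparison
#'
#' Captures the metadata needed to name the pair of gene sets derived from one
#' comparison: the two group labels (group 1 is the condition of interest,
#' group 2 the reference), the species, free-order descriptor tokens
#' (age/timepoint, tissue, gender, ...), a provenance identifier (e.g. a
#' series accession) and a numeric collection ID.
#'
#' Descriptor tokens are kept as an ordered, opaque list: the naming
#' convention allows them in any order, so no semantic typing is attempted.
#' Group and species labels may contain underscores, but `"___"` (the segment
#' separator) is forbidden everywhere and `"_v_"` is forbidden inside group
#' labels so that names parse back unambiguously.
#'
#' @param group1,group2 Non-empty group labels.
#' @param species Non-empty species label (single token, no underscores).
#' @param descriptors Character vector of descriptor tokens (may be empty).
#'   Purely numeric tokens are rejected since the trailing numeric token of a
#'   name is reserved for the ID.
#' @param source_id Provenance identifier stored in the GMT info field.
#' @param mgs_id Positive integer ID, unique within a collection.
#' @return An object of class `comparison_meta`.
#' @export
comparison_meta <- function(group1, group2, species,
                            descriptors = character(),
                            source_id = "", mgs_id) {
  chk <- function(x, what) {
    if (!is.character(x) || length(x) != 1L || !nzchar(x)) {
      stopf("'%s' must be a single non-empty string", what)
    }
  }
  chk(group1, "group1"); chk(group2, "group2"); chk(species, "species")
  descriptors <- as.character(descriptors)
  all_tokens <- c(group1, group2, species, descriptors)
  if (any(grepl("___", all_tokens, fixed = TRUE))) {
    stopf("'___' is reserved as the name segment separator")
  }
  if (any(grepl("_v_", c(group1, group2), fixed = TRUE))) {
    stopf("group labels must not contain '_v_'")
  }
  if (grepl("_", species, fixed = TRUE)) {
    stopf("species must be a single token (no underscores)")
  }
  if (any(grepl("^[0-9]+$", descriptors))) {
    stopf("descriptor tokens must not be purely numeric (reserved for the ID)")
  }
  if (!is_count(mgs_id)) stopf("'mgs_id' must be a positive integer")
  structure(list(group1 = group1, group2 = group2, species = species,
                 descriptors = descriptors, source_id = source_id,
                 mgs_id = as.integer(mgs_id)),
            class = "comparison_meta")
}

#' Build a gene-set name from comparison metadata
#'
#' Names follow the convention
#' `<direction>_in_<group1>_v_<group2>___<species>_<descriptors>_<id>`:
#' before the triple underscore, `up_in_Group1_v_Group2` (or `down_in_...`)
#' states that the genes are more (or less) expressed in group 1 than in
#' group 2; after it come the species, the descriptor tokens in their given
#' order, and finally the numeric set ID.
#'
#' @param meta A [comparison_meta()].
#' @param direction `"up"` or `"down"`.
#' @return The set name as a string.
#' @seealso [parse_set_name()]
#' @export
#' @examples
#' m <- comparison_meta("mdx", "WT", "mouse", c("8wk", "gastroc"),
#'                      "GSE123", 42)
#' build_set_name(m, "up")  # "up_in_mdx_v_WT___mouse_8wk_gastroc_42"
build_set_name <- function(meta, direction = c("up", "down")) {
  stopifnot(inherits(meta, "comparison_meta"))
  direction <- match.arg(direction)
  tail_tokens <- c(meta$species, meta$descriptors, meta$mgs_id)
  paste0(direction, "_in_", meta$group1, "_v_", meta$group2, "___",
         paste(tail_tokens, collapse = "_"))
}

#' Parse a gene-set name built with the standard convention
#'
#' Splits on `"___"`; the first segment must match
#' `(up|down)_in_<group1>_v_<group2>` (the last `_v_` separates the groups),
#' and in the second segment the first underscore-delimited token is the
#' species, the final numeric token is the ID, and everything between is
#' returned as descriptor tokens.
#'
#' @param name A set name.
#' @return A list with elements `direction`, `group1`, `group2`, `species`,
#'   `descriptors`, `mgs_id`.
#' @export
parse_set_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  segs <- strsplit(name, "___", fixed = TRUE)[[1]]
  if (length(segs) != 2L) {
    stopf("set name parse error: expected exactly one '___' separator in '%s'",
          name)
  }
  m <- regmatches(segs[1],
                  regexec("^(up|down)_in_(.+)_v_(.+)$", segs[1]))[[1]]
  if (length(m) != 4L) {
    stopf("set name parse error: first segment of '%s' does not match '(up|down)_in_<group1>_v_<group2>'",
          name)
  }
  tokens <- strsplit(segs[2], "_", fixed = TRUE)[[1]]
  if (length(tokens) < 2L) {
    stopf("set name parse error: second segment of '%s' needs at least a species and an ID",
          name)
  }
  id_tok <- tokens[length(tokens)]
  if (!grepl("^[0-9]+$", id_tok)) {
    stopf("set name parse error: final token '%s' of '%s' is not numeric",
          id_tok, name)
  }
  list(direction = m[2], group1 = m[3], group2 = m[4],
       species = tokens[1],
       descriptors = tokens[-c(1L, length(tokens))],
       mgs_id = as.integer(id_tok))
}

#' Name a consensus set
#'
#' Consensus sets are named `<tag>__<category><percent>`, e.g.
#' `HumanSkelMusc_DMD_v_Healthy__up50` for genes upregulated in at least 50%
#' of the contributing studies of that comparison.
#'
#' @param tag Comparison tag (tissue type and contrast).
#' @param category `"up"`, `"down"` or `"same"`.
#' @param threshold Support threshold in (0, 1].
#' @return The consensus set name.
#' @seealso [parse_consensus_name()]
#' @export
consensus_name <- function(tag, category = c("up", "down", "same"),
                           threshold) {
  if (!is.character(tag) || length(tag) != 1L || !nzchar(tag)) {
    stopf("'tag' must be a single non-empty string")
  }
  if (grepl("__", tag, fixed = TRUE)) {
    stopf("consensus tag must not contain '__'")
  }
  category <- match.arg(category)
  stopifnot(is_scalar_number(threshold), threshold > 0, threshold <= 1)
  pct <- round(threshold * 100)
  paste0(tag, "__", category, pct)
}

#' Parse a consensus set name
#'
#' @param name A name produced by [consensus_name()].
#' @return A list with elements `tag`, `category`, `threshold`.
#' @export
parse_consensus_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  m <- regmatches(name,
                  regexec("^(.+)__(up|down|same)([0-9]+)$", name))[[1]]
  if (length(m) != 4L) {
    stopf("consensus name parse error: '%s' does not match '<tag>__<category><percent>'",
          name)
  }
  list(tag = m[2], category = m[3],
       threshold = as.numeric(m[4]) / 100)
}
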