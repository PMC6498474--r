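#' @keywords internal
"_PACKAGE"

# Run `code` under a temporary RNG state seeded with `seed`, restoring the
# caller's RNG stream afterwards. All stochastic entry points funnel through
# this so that equal seeds give equal outputs without clobbering user state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else {
      NULL
    }
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(as.integer(seed))
  }
  force(code)
}

# Row medians of a numeric matrix, vectorised via a single order() pass
# (no per-row apply). Used in the hot paths of RLE and NUSE.
row_medians <- function(m) {
  n <- nrow(m)
  k <- ncol(m)
  if (k == 1L) return(as.numeric(m[, 1L]))
  sorted <- matrix(m[order(row(m), m)], nrow = n, ncol = k, byrow = TRUE)
  if (k %% 2L == 1L) {
    sorted[, (k + 1L) %/% 2L]
  } else {
    (sorted[, k %/% 2L] + sorted[, k %/% 2L + 1L]) / 2
  }
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x >= 1 && x == floor(x)
}

is_scalar_number <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x)
}
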