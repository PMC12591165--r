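# Internal helpers shared across modules.

#' Evaluate code with a temporary RNG seed
#'
#' Sets the RNG seed, runs `code`, and restores the caller's RNG state, so
#' seeded operations never perturb the global random stream.
#'
#' @param seed Integer seed.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
#' @noRd
with_seed <- function(seed, code) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv(), inherits = FALSE)
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
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

#' Derive a per-stage seed from a root seed
#'
#' All pipeline randomness flows from one root seed; each stage gets a
#' deterministic sub-seed keyed by its name, so stages can be rerun in
#' isolation.
#'
#' @param seed Root integer seed.
#' @param stage Stage name (character scalar).
#' @return An integer seed below 2^31.
#' @export
stage_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L)
  key <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 48271 + key) %% 2147483587) + 1L
}

# Canonical experimental group labels, in display order.
GROUP_LEVELS <- c("young_vehicle", "aged_vehicle", "aged_treated")

abort_ctx <- function(stage, msg) {
  stop(sprintf("[%s] %s", stage, msg), call. = FALSE)
}

# Coerce base or Matrix inputs to a numeric column-sparse dgCMatrix.
as_sparse_counts <- function(m) {
  methods::as(Matrix::Matrix(m, sparse = TRUE), "CsparseMatrix")
}
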