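#' Derive a reproducible sub-seed from a master seed and a tag
#'
#' Pipelines take one master seed; every stochastic operation derives its own
#' substream from the master seed plus a short operation tag, so that adding
#' or reordering one stage never perturbs the draws of another. The result is
#' always a valid 32-bit R integer.
#'
#' @param seed integer master seed.
#' @param tag character scalar naming the operation (and, if needed, a call
#'   index, e.g. `"skewers:3"`).
#' @return an integer in `[0, 2^31 - 2]`.
#' @export
substream_seed <- function(seed, tag) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(tag))
  h <- sum(utf8ToInt(tag) * seq_along(utf8ToInt(tag)))
  as.integer((abs(seed) * 69069 + h * 2654435761) %% (2^31 - 1))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run an expression under a local RNG seed
#'
#' Saves and restores `.Random.seed` so seeded operations do not disturb the
#' caller's RNG stream.
#' @noRd
with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

check_square_symmetric <- function(M, tol = 1e-12, what = "matrix") {
  if (!is.matrix(M) || nrow(M) != ncol(M)) {
    stop(what, " must be a square matrix", call. = FALSE)
  }
  if (max(abs(M - t(M))) > tol * max(1, max(abs(M)))) {
    stop(what, " must be symmetric (within ", format(tol), ")", call. = FALSE)
  }
  invisible(TRUE)
}
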