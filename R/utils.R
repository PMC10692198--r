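# Internal helpers shared across modules.

#' Evaluate an expression with a private RNG stream
#'
#' Saves the caller's `.Random.seed`, seeds a local Mersenne-Twister stream,
#' evaluates `expr`, and restores the caller's state, so that seeded package
#' functions never disturb user-level random number generation.
#'
#' @param seed integer seed for the local stream.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
#' @noRd
with_local_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% .Machine$integer.max))
  expr
}

# Deterministic fan-out of one master seed into per-replicate seeds,
# kept below 2^31.
derive_seeds <- function(seed, n) {
  (as.numeric(seed) + 7919 * seq_len(n)) %% 2147483647
}

#' Geometric mean
#'
#' Geometric mean of a positive vector; the standard summary for
#' effective-size trajectories over a range of generations.
#'
#' @param x positive numeric vector.
#' @return `exp(mean(log(x)))`.
#' @export
geomean <- function(x) exp(mean(log(x)))

`%||%` <- function(a, b) if (is.null(a)) b else a

stop_input <- function(...) stop(..., call. = FALSE)

# Small TSV helpers: all on-disk artefacts are tab-separated text.
write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

read_tsv <- function(path, ...) {
  utils::read.table(path, sep = "\t", header = TRUE,
                    stringsAsFactors = FALSE, ...)
}
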