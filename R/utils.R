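# Shared helpers: seed substreams, RNG hygiene, window iteration.

#' Derive a named substream seed from a root seed
#'
#' All stochastic stages draw their seeds from one root seed through named
#' substreams, so a stage can be rerun in isolation and still reproduce the
#' run it belonged to.
#'
#' @param seed integer root seed
#' @param name substream name, e.g. `"folds"` or `"split"`
#' @param index optional replicate index folded into the stream
#' @return an integer seed below 2^31.
#' @export
substreamSeed <- function(seed, name, index = 0L) {
  h <- sum(utf8ToInt(name) * seq_along(utf8ToInt(name)))
  as.integer((as.numeric(seed) * 48271 + h * 1299721 + index * 7919) %%
               2147483629)
}

# Evaluate `expr` under `seed` without disturbing the caller's RNG state.
withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  expr
}

#' Tile sliding windows over a chromosome
#'
#' Shared window iterator used by the genome scan (windows defined in variant
#' counts) and by the refinement pass and LD pruning (windows defined in bp).
#' Coordinates are 1-based and windows are inclusive on both ends.  The last
#' window is truncated at the chromosome end and reported as-is; callers
#' apply their own minimum-size rule.
#'
#' @param n extent: number of variants (`unit = "count"`) or the last bp
#'   position (`unit = "bp"`)
#' @param window window size in the same unit
#' @param step shift between consecutive window starts
#' @param unit `"count"` or `"bp"`
#' @return data.frame with `start`, `end` (inclusive, 1-based).
#' @export
slidingWindows <- function(n, window, step = window, unit = c("count", "bp")) {
  unit <- match.arg(unit)
  stopifnot(window >= 1, step >= 1, n >= 1)
  starts <- seq.int(1L, max(1L, n), by = step)
  ends <- pmin(starts + window - 1L, n)
  # drop windows fully contained in their predecessor (trailing stubs)
  keep <- c(TRUE, ends[-1L] > ends[-length(ends)])
  data.frame(start = starts[keep], end = ends[keep])
}

# solve a symmetric PD system via cholesky, with a diagnostic error
cholSolve <- function(M, b) {
  R <- tryCatch(chol(M), error = function(e)
    stop("system matrix is not positive definite", call. = FALSE))
  backsolve(R, forwardsolve(t(R), b))
}
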