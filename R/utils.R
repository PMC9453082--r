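#' Evaluate an expression under a local random seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state on exit. All randomised functions in
#' the package route their sampling through this helper so that no global
#' random state leaks between calls and identical seeds give identical
#' output.
#'
#' @param seed Single integer seed.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("'seed' must be a single integer", call. = FALSE)
  }
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
  set.seed(as.integer(seed))
  expr
}

# scalar argument checks used across modules
.check_scalar <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < lower || x > upper) {
    stop(sprintf("'%s' must be a single number in [%s, %s]", name, lower, upper),
         call. = FALSE)
  }
  invisible(x)
}

# uppercase and validate a DNA string against {A,C,G,T,N}
.validate_bases <- function(x, what = "sequence") {
  x <- toupper(x)
  bad <- grepl("[^ACGTN]", x)
  if (any(bad)) {
    stop(sprintf("%s contains characters outside {A,C,G,T,N} (first offender: record %d)",
                 what, which(bad)[1L]), call. = FALSE)
  }
  x
}
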