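#' Evaluate an expression under a temporary RNG seed
#'
#' Saves the caller's RNG state, seeds the generator, evaluates `expr`,
#' and restores the previous state, so library internals never perturb a
#' user's random stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
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
  expr
}

#' Derive a stage/unit seed from a global seed
#'
#' Deterministic integer mixing so that one global seed yields an
#' independent, reproducible stream per pipeline stage and per generated
#' unit.  Kept below 2^31 so the result is a valid R integer seed.
#'
#' @param seed global integer seed.
#' @param ... integers or strings identifying the consumer (stage name,
#'   subject index, ...). Strings are hashed by character codes.
#' @return integer seed.
#' @keywords internal
derive_seed <- function(seed, ...) {
  parts <- list(...)
  h <- as.double(seed) %% 2147483647
  for (p in parts) {
    if (is.character(p)) {
      for (cc in utf8ToInt(paste(p, collapse = "/"))) {
        h <- (h * 69069 + cc) %% 2147483647
      }
    } else {
      for (v in as.double(p)) h <- (h * 69069 + v + 1) %% 2147483647
    }
  }
  as.integer(h %% 2147483629 + 1)
}

stop_invalid <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

#' Format numbers so text serialization round-trips exactly
#' @keywords internal
format_full <- function(x) {
  sprintf("%.17g", x)
}

assert_finite_numeric <- function(x, what) {
  if (!is.numeric(x) || length(x) < 1 || !all(is.finite(x))) {
    stop_invalid("%s must be a non-empty finite numeric vector", what)
  }
  invisible(x)
}
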