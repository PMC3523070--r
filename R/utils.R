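# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Evaluate code under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded operations inside the
#' package never disturb the caller's RNG stream.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return the value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
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
  force(code)
}

#' Derive a stage-local seed from a global seed
#'
#' Deterministic, stage-name-keyed derivation so that pipeline stages draw
#' independent but reproducible random streams from one configured seed.
#' The result is always a valid 32-bit integer seed.
#'
#' @param seed global integer seed.
#' @param stage character stage name.
#' @return integer seed.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.character(stage), length(stage) == 1L, nzchar(stage))
  codes <- utf8ToInt(stage)
  h <- sum(codes * seq_along(codes)) %% 99991L
  as.integer((abs(as.numeric(seed)) * 7919 + h * 104729) %% 2147483647) + 1L
}

# Format doubles so a write -> read TSV round-trip is bitwise exact.
format_full <- function(x) {
  out <- sprintf("%.17g", x)
  out[is.na(x)] <- "NA"
  out
}

stop_with <- function(...) stop(sprintf(...), call. = FALSE)

# Trapezoid rule, used to check that density grids integrate to ~1.
trapz <- function(x, y) sum(diff(x) * (utils::head(y, -1) + utils::tail(y, -1)) / 2)
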