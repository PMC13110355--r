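#' @keywords internal
"_PACKAGE"

# Argument checking helpers shared across modules. These fail loudly and
# early: all user-facing errors should name the offending argument.

stop_if_not_number <- function(x, name, lower = -Inf, upper = Inf,
                               allow_na = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (!allow_na && is.na(x))) {
    stop(sprintf("`%s` must be a single finite number", name), call. = FALSE)
  }
  if (!is.na(x) && (x < lower || x > upper)) {
    stop(sprintf("`%s` must be in [%g, %g], got %g", name, lower, upper, x),
         call. = FALSE)
  }
  invisible(x)
}

stop_if_not_count <- function(x, name, lower = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x != as.integer(x)) {
    stop(sprintf("`%s` must be a single integer", name), call. = FALSE)
  }
  if (x < lower) {
    stop(sprintf("`%s` must be >= %d", name, lower), call. = FALSE)
  }
  invisible(as.integer(x))
}

#' Derive reproducible sub-seeds from a session seed
#'
#' A single session seed is expanded into independent per-unit seeds so that
#' trial-level reproducibility survives reordering of the work.
#'
#' @param seed Integer master seed.
#' @param n Number of sub-seeds to draw.
#' @return Integer vector of length `n`, each in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(seed, n) {
  stop_if_not_count(seed, "seed", lower = 0L)
  stop_if_not_count(n, "n", lower = 1L)
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  sample.int(.Machine$integer.max - 1L, n)
}

with_seed <- function(seed, expr) {
  old <- globalenv()$.Random.seed
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}
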