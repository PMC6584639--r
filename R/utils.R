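#' @keywords internal
"_PACKAGE"

# Run `expr` under a fixed RNG seed without disturbing the caller's RNG state.
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, seed >= 0, seed == floor(seed))
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

stop_param <- function(...) stop(sprintf(...), call. = FALSE)

check_fraction <- function(x, name, allow_zero = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || x < 0 || x > 1 ||
      (!allow_zero && x == 0))
    stop_param("`%s` must be a single value in %s", name,
               if (allow_zero) "[0, 1]" else "(0, 1]")
  invisible(x)
}

check_positive <- function(x, name, strict = TRUE) {
  if (!is.numeric(x) || length(x) != 1 || is.na(x) || !is.finite(x) ||
      (strict && x <= 0) || (!strict && x < 0))
    stop_param("`%s` must be a single %s number", name,
               if (strict) "positive" else "non-negative")
  invisible(x)
}
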