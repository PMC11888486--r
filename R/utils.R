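# internal helpers

`%||%` <- function(x, y) if (is.null(x)) y else x

#' Evaluate code under a temporary RNG seed
#'
#' Sets the Mersenne-Twister seed, runs `code`, and restores the caller's RNG
#' state on exit, so seeded simulation never perturbs the global stream.
#'
#' @param seed Integer seed (kept below 2^31).
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv, inherits = FALSE)
  on.exit({
    if (had) assign(".Random.seed", old, envir = genv)
    else if (exists(".Random.seed", envir = genv, inherits = FALSE))
      rm(".Random.seed", envir = genv)
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  force(code)
}

stop_cytocsf <- function(...) stop(..., call. = FALSE)

assert_nonneg <- function(x, what) {
  if (any(!is.finite(x) & !is.na(x)) || any(x < 0, na.rm = TRUE))
    stop_cytocsf(what, " must be non-negative")
  invisible(x)
}

assert_pct <- function(x, what) {
  assert_nonneg(x, what)
  if (any(x > 100, na.rm = TRUE))
    stop_cytocsf(what, " must lie in [0, 100]")
  invisible(x)
}
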