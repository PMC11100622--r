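# internal helpers: argument checking and seeded randomness

stop_if_not_scalar_pos <- function(x, name, allow_zero = FALSE) {
  ok <- is.numeric(x) && length(x) == 1L && is.finite(x) &&
    (if (allow_zero) x >= 0 else x > 0)
  if (!ok) {
    stop(sprintf("`%s` must be a single %s number",
                 name, if (allow_zero) "non-negative" else "positive"),
         call. = FALSE)
  }
  invisible(x)
}

# Run `expr` under a fixed seed without disturbing the caller's RNG stream.
# With seed = NULL the expression uses (and advances) the global stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single integer or NULL", call. = FALSE)
  }
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  expr
}

# coefficient of determination, defined as 1 for a zero-variance response
# (avoids summary.lm's perfect-fit warning on exact worked examples)
r_squared <- function(y, fit) {
  ss_tot <- sum((y - mean(y))^2)
  if (ss_tot == 0) return(1)
  1 - sum(stats::residuals(fit)^2) / ss_tot
}

# names used for burst boundaries throughout the package
PHASE_NAMES <- c("pd_off", "lp_on", "lp_off", "py_on", "py_off")
UNIT_NAMES <- c("PD", "LP", "PY")
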