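# Internal helpers shared across modules.

# CT attenuation scale limits (12-bit Hounsfield range).
HU_MIN <- -1024
HU_MAX <- 3071

`%||%` <- function(a, b) if (is.null(a)) b else a

# Commercial rounding used for printed percentages: 0.5 always rounds away
# from zero (for the non-negative quantities reported here, upward).
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# Structured conditions: every package error carries a subclass
# ("lsvar_<subclass>") so callers and the CLI can dispatch on it.
stop_lsvar <- function(subclass, message, call. = sys.call(-1)) {
  cond <- structure(
    class = c(paste0("lsvar_", subclass), "lsvar_error", "error", "condition"),
    list(message = message, call = call.)
  )
  stop(cond)
}

warn_lsvar <- function(subclass, message) {
  cond <- structure(
    class = c(paste0("lsvar_", subclass), "lsvar_warning", "warning", "condition"),
    list(message = message, call = sys.call(-1))
  )
  warning(cond)
}

# Evaluate `expr` under a fixed RNG seed without disturbing the caller's
# random stream.  seed = NULL runs `expr` on the ambient stream.
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!is.numeric(seed) || length(seed) != 1 || !is.finite(seed)) {
    stop_lsvar("config_error", "`seed` must be a single finite number or NULL")
  }
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      suppressWarnings(rm(".Random.seed", envir = globalenv())),
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

check_finite_hu <- function(x, what) {
  xx <- x[!is.na(x)]
  if (any(!is.finite(xx)) || any(xx < HU_MIN | xx > HU_MAX)) {
    stop_lsvar(
      "invalid_measurement",
      sprintf(
        "%s must be finite HU values within [%d, %d]", what, HU_MIN, HU_MAX
      )
    )
  }
  invisible(x)
}
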