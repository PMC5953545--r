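# Internal helpers shared across modules.

# Evaluate `code` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed)) {
    stop("`seed` must be a single finite number", call. = FALSE)
  }
  genv <- globalenv()
  had <- exists(".Random.seed", envir = genv, inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = genv) else NULL
  on.exit({
    if (had) {
      assign(".Random.seed", old, envir = genv)
    } else if (exists(".Random.seed", envir = genv, inherits = FALSE)) {
      rm(".Random.seed", envir = genv)
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  force(code)
}

check_finite <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(!is.finite(x))) {
    stop(sprintf("`%s` must be finite and numeric", name), call. = FALSE)
  }
  invisible(x)
}

check_nonneg <- function(x, name) {
  check_finite(x, name)
  if (any(x < 0)) {
    stop(sprintf("`%s` must be non-negative", name), call. = FALSE)
  }
  invisible(x)
}

check_positive <- function(x, name) {
  check_finite(x, name)
  if (any(x <= 0)) {
    stop(sprintf("`%s` must be strictly positive", name), call. = FALSE)
  }
  invisible(x)
}

# Population (1/n) or sample (1/(n-1)) standard deviation.
sd_by_type <- function(x, type = c("population", "sample")) {
  type <- match.arg(type)
  n <- length(x)
  if (n == 0L) return(NA_real_)
  if (type == "sample") return(stats::sd(x))
  sqrt(sum((x - mean(x))^2) / n)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
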