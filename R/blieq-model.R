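#' Fit the steady-state binding curve
#'
#' Nonlinear least squares of the single-site hyperbola
#' \deqn{r_{eq} = r_0 + (r_{max} - r_0)\,\frac{x}{K_d + x}}
#' to equilibrium responses versus analyte concentration. Standard errors
#' are asymptotic (Jacobian-based).
#'
#' @param conc analyte concentrations (uM), at least 3 distinct values.
#' @param req equilibrium responses (response units).
#' @return An object of class `"bli_fit"` with `kd`, `r0`, `rmax`, their
#'   standard errors (`se`), the `curve` data, and `converged`. Methods:
#'   `print`, `summary`, `coef`, `predict`, `plot`, `fitted`,
#'   `residuals`.
#' @examples
#' x <- c(0.3, 0.6, 1.3, 2.5, 5, 10, 20)
#' fit_equilibrium(x, x / (7 + x))
#' @export
fit_equilibrium <- function(conc, req) {
  check_positive(conc, "conc")
  check_finite(req, "req")
  stopifnot(length(conc) == length(req))
  if (length(unique(conc)) < 3L) {
    stop("need at least 3 distinct analyte concentrations", call. = FALSE)
  }
  df <- data.frame(x = conc, r = req)
  resid_fn <- function(p) {
    req - (p["r0"] + (p["rmax"] - p["r0"]) * conc / (p["kd"] + conc))
  }
  start <- c(kd = stats::median(conc), r0 = min(req),
             rmax = max(req) + 0.1 * diff(range(req)) + 1e-6)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      start, lower = c(kd = 1e-9, r0 = -Inf, rmax = -Inf),
      fn = resid_fn,
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-12, ptol = 1e-12)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) {
    out <- list(kd = NA_real_, r0 = NA_real_, rmax = NA_real_,
                se = c(kd = NA_real_, r0 = NA_real_, rmax = NA_real_),
                curve = df, converged = FALSE, flags = character())
    class(out) <- "bli_fit"
    return(out)
  }
  cf <- fit$par
  # asymptotic standard errors from the analytic Jacobian
  f <- conc / (cf["kd"] + conc)
  J <- cbind(kd = -(cf["rmax"] - cf["r0"]) * conc / (cf["kd"] + conc)^2,
             r0 = 1 - f, rmax = f)
  dof <- max(length(conc) - 3L, 1L)
  sigma2 <- sum(resid_fn(cf)^2) / dof
  se <- tryCatch(sqrt(diag(sigma2 * solve(crossprod(J)))),
                 error = function(e)
                   setNames(rep(NA_real_, 3L), colnames(J)))
  out <- list(kd = unname(cf["kd"]), r0 = unname(cf["r0"]),
              rmax = unname(cf["rmax"]),
              se = c(kd = unname(se["kd"]), r0 = unname(se["r0"]),
                     rmax = unname(se["rmax"])),
              curve = df, converged = TRUE, flags = character())
  class(out) <- "bli_fit"
  out
}

#' @export
print.bli_fit <- function(x, digits = 3, ...) {
  cat("Steady-state BLI fit (single-site hyperbola)\n")
  if (!x$converged) {
    cat("  fit did not converge\n")
    return(invisible(x))
  }
  cat(sprintf("  Kd   = %s ± %s uM\n", format(signif(x$kd, digits)),
              format(signif(x$se["kd"], 2))))
  cat(sprintf("  r0   = %s, rmax = %s (response units)\n",
              format(signif(x$r0, digits)),
              format(signif(x$rmax, digits))))
  cat(sprintf("  %d concentrations: %s uM\n", nrow(x$curve),
              paste(sort(unique(x$curve$x), decreasing = TRUE),
                    collapse = ", ")))
  if (length(x$flags)) {
    cat("  flags:", paste(x$flags, collapse = "; "), "\n")
  }
  invisible(x)
}

#' @export
summary.bli_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.bli_fit")
}

#' @export
print.summary.bli_fit <- function(x, ...) {
  print(x$fit)
  cat("\nEquilibrium responses:\n")
  print(x$fit$curve, row.names = FALSE)
  invisible(x)
}

#' @export
coef.bli_fit <- function(object, ...) {
  c(kd = object$kd, r0 = object$r0, rmax = object$rmax)
}

#' @export
predict.bli_fit <- function(object, newdata = NULL, ...) {
  x <- if (is.null(newdata)) object$curve$x else
    (if (is.data.frame(newdata)) newdata$x else newdata)
  object$r0 + (object$rmax - object$r0) * x / (object$kd + x)
}

#' @export
fitted.bli_fit <- function(object, ...) predict(object)

#' @export
residuals.bli_fit <- function(object, ...) {
  object$curve$r - predict(object)
}

#' @export
plot.bli_fit <- function(x, ...) {
  grid <- seq(0, max(x$curve$x) * 1.05, length.out = 200)
  plot(x$curve$x, x$curve$r, pch = 19, xlab = "analyte (uM)",
       ylab = expression(r[eq] ~ "(response units)"), ...)
  lines(grid, predict(x, grid))
  abline(v = x$kd, lty = 3)
  mtext(sprintf("Kd = %.3g uM", x$kd), side = 3, line = 0.2, cex = 0.9)
  invisible(x)
}

#' @export
simulate.bli_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  mu <- predict(object)
  sigma <- stats::sd(residuals(object))
  replicate(nsim, mu + rnorm(length(mu), 0, sigma), simplify = FALSE)
}

#' Run the full BLI analysis pipeline
#'
#' For every sample channel: reference subtraction
#' ([subtract_reference()]), baseline alignment ([align_baseline()]),
#' Savitzky-Golay smoothing ([sg_smooth()]), steady-state response
#' extraction ([equilibrium_response()]); then the hyperbolic fit
#' ([fit_equilibrium()]) across the concentration ladder. Channels whose
#' association phase has not plateaued are flagged in the result but not
#' dropped.
#'
#' @param set a `"bli_set"` (see [simulate_bli()], [read_sensorgrams()]).
#' @param scheme referencing scheme, `"double"` (default) or `"single"`.
#' @param sg_window,sg_order Savitzky-Golay parameters.
#' @param baseline_window,eq_window alignment and steady-state windows
#'   (s).
#' @param json optional path for a JSON report.
#' @return A `"bli_fit"` augmented with the per-concentration `curve`
#'   and plateau `flags`.
#' @export
run_bli_analysis <- function(set, scheme = c("double", "single"),
                             sg_window = 15, sg_order = 2,
                             baseline_window = 10, eq_window = 20,
                             json = NULL) {
  scheme <- match.arg(scheme)
  stopifnot(inherits(set, "bli_set"))
  roles <- vapply(set, attr, "", "role")
  samples <- set[roles == "sample"]
  if (!length(samples)) {
    stop("sensorgram set contains no sample channels", call. = FALSE)
  }
  loaded <- set[roles == "reference"]
  if (!length(loaded)) {
    stop("sensorgram set contains no loaded reference channel",
         call. = FALSE)
  }
  unloaded <- set[roles == "double_reference"]
  unloaded_conc <- vapply(unloaded, attr, 0, "analyte_conc")
  conc <- req <- numeric(length(samples))
  flags <- character()
  for (i in seq_along(samples)) {
    g <- samples[[i]]
    conc[i] <- attr(g, "analyte_conc")
    uref <- NULL
    if (scheme == "double") {
      j <- which(abs(unloaded_conc - conc[i]) < 1e-9)
      if (!length(j)) {
        stop(sprintf(
          "scheme `double`: no unloaded reference for %g uM analyte",
          conc[i]), call. = FALSE)
      }
      uref <- unloaded[[j[1]]]
    }
    g <- subtract_reference(g, loaded[[1]], uref, scheme)
    g <- align_baseline(g, baseline_window)
    g <- sg_smooth(g, sg_window, sg_order)
    req[i] <- equilibrium_response(g, eq_window)
    if (!is_plateaued(g, eq_window)) {
      flags <- c(flags, sprintf("channel %g uM: association not plateaued",
                                conc[i]))
    }
  }
  fit <- fit_equilibrium(conc, req)
  fit$flags <- flags
  fit$scheme <- scheme
  if (length(flags)) {
    warning(paste(flags, collapse = "; "), call. = FALSE)
  }
  if (!is.null(json)) {
    jsonlite::write_json(
      list(kd = fit$kd, r0 = fit$r0, rmax = fit$rmax,
           se = as.list(fit$se), scheme = scheme,
           r_eq = fit$curve, flags = flags),
      json, auto_unbox = TRUE, digits = NA)
  }
  fit
}

#' @rdname run_bli_analysis
#' @export
fit_bli <- run_bli_analysis
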