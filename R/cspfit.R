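#' Composite chemical-shift perturbation
#'
#' Combines 1H and 15N shift changes into a single perturbation:
#' \deqn{\Delta\delta = \sqrt{\Delta\delta_H^2 + (0.154\,\Delta\delta_N)^2}}
#' The 0.154 factor rescales the 15N dimension to the 1H shift range.
#'
#' @param dh,dn shift changes in ppm (1H and 15N); vectorized.
#' @param nscale 15N scaling factor.
#' @return Composite shift difference (ppm), non-negative and symmetric
#'   in the sign of both arguments.
#' @examples
#' composite_csp(0.03, 0.2)
#' @export
composite_csp <- function(dh, dn, nscale = 0.154) {
  check_finite(dh, "dh")
  check_finite(dn, "dn")
  sqrt(dh^2 + (nscale * dn)^2)
}

#' Per-residue CSP profile of a titration
#'
#' Computes the composite shift difference of every residue at every
#' titration point relative to the apo point. Residues whose peak is
#' unobservable at the evaluation point (typically broadened beyond
#' detection) are flagged and excluded from downstream statistics, never
#' imputed.
#'
#' @param series a `"titration_series"`.
#' @param eval_point index of the point at which significance statistics
#'   are evaluated; default the final point.
#' @param nscale 15N scaling passed to [composite_csp()].
#' @return A `"csp_profile"`: list with `residues`, `dd` (residue x
#'   point matrix, `NA` where unobserved), `dd_eval`, logical
#'   `broadened`, concentrations and `eval_point`.
#' @export
csp_profile <- function(series, eval_point = NULL, nscale = 0.154) {
  stopifnot(inherits(series, "titration_series"))
  if (any(is.na(series$h[, 1]))) {
    stop("every residue must be observed at the apo point", call. = FALSE)
  }
  np <- length(series$l_conc)
  eval_point <- as.integer(eval_point %||% np)
  stopifnot(eval_point >= 1L, eval_point <= np)
  dh <- series$h - series$h[, 1]
  dn <- series$n - series$n[, 1]
  # composite shift with NA pass-through for unobserved peaks
  dd <- sqrt(dh^2 + (nscale * dn)^2)
  broadened <- is.na(dd[, eval_point])
  if (any(broadened)) {
    warning(sprintf("%d residue(s) unobserved at the evaluation point: %s",
                    sum(broadened),
                    paste(series$residues[broadened], collapse = ", ")),
            call. = FALSE)
  }
  structure(
    list(residues = series$residues, dd = dd,
         dd_eval = dd[, eval_point], broadened = broadened,
         p_conc = series$p_conc, l_conc = series$l_conc,
         eval_point = eval_point),
    class = "csp_profile")
}

#' @export
print.csp_profile <- function(x, ...) {
  cat(sprintf(
    "CSP profile: %d residues, %d points (evaluated at point %d)\n",
    length(x$residues), length(x$l_conc), x$eval_point))
  ok <- !x$broadened
  cat(sprintf("  max %s = %.4f ppm, mean = %.4f ppm (%d usable residues)\n",
              "Δδ", max(x$dd_eval[ok]), mean(x$dd_eval[ok]),
              sum(ok)))
  invisible(x)
}

#' Select significantly perturbed residues
#'
#' A residue is significant when its composite shift at the evaluation
#' point strictly exceeds the mean plus `k` standard deviations of the
#' shifts of all unflagged residues. The default `k = 0.5` is the
#' permissive cutoff appropriate for a small domain whose binding
#' interface is a large fraction of its surface.
#'
#' @param profile a `"csp_profile"`.
#' @param k standard-deviation multiplier.
#' @param sd_type `"population"` (1/n, default) or `"sample"` (1/(n-1)).
#' @return Character vector of significant residue identifiers
#'   (possibly empty); the threshold is attached as attribute
#'   `"threshold"`.
#' @export
select_significant <- function(profile, k = 0.5,
                               sd_type = c("population", "sample")) {
  stopifnot(inherits(profile, "csp_profile"))
  sd_type <- match.arg(sd_type)
  ok <- !profile$broadened
  if (sum(ok) < 2L) {
    stop("need at least 2 unflagged residues", call. = FALSE)
  }
  dd <- profile$dd_eval[ok]
  thr <- mean(dd) + k * sd_by_type(dd, sd_type)
  sel <- profile$residues[ok][dd > thr]
  attr(sel, "threshold") <- thr
  sel
}

#' Fit a single residue's binding isotherm
#'
#' Nonlinear least squares of the ligand-depleted single-site model
#' \deqn{\Delta\delta = \Delta\delta_{max}
#'   \frac{(L+P+K_d) - \sqrt{(L+P+K_d)^2 - 4PL}}{2P}}
#' with both the ligand and protein concentrations as independent
#' variables, so dilution of the observed protein across the titration is
#' accounted for. Fitting uses bounded Levenberg-Marquardt; start values
#' are `Kd = median(L > 0)` and `ddmax = 1.2 max(dd)`, with bounds
#' `Kd in (0, 1e6]` uM and `ddmax in (0, 10]` ppm.
#'
#' @param dd per-point composite shift differences (ppm; `NA` allowed).
#' @param P,L per-point protein and ligand concentrations (uM).
#' @return List with `kd`, `ddmax`, `residual` (sum of squares),
#'   `converged`, and `fitted` values. Non-convergence and degenerate
#'   flat series are flagged (`converged = FALSE`), never silently
#'   reported as estimates.
#' @export
fit_residue <- function(dd, P, L) {
  keep <- !is.na(dd)
  dd <- dd[keep]; P <- P[keep]; L <- L[keep]
  if (sum(L > 0) < 3L) {
    stop("need at least 3 titration points with L > 0", call. = FALSE)
  }
  out <- list(kd = NA_real_, ddmax = NA_real_, residual = NA_real_,
              converged = FALSE, fitted = rep(NA_real_, length(dd)))
  if (max(dd) < 1e-8) return(out)  # flat series: nothing to fit
  model <- function(p) {
    b <- L + P + p["kd"]
    disc <- pmax(b^2 - 4 * P * L, 0)
    p["ddmax"] * (b - sqrt(disc)) / (2 * P)
  }
  # coarse multi-start over log-spaced Kd (ddmax profiled linearly),
  # guarding against the shallow near-stoichiometric basin at Kd << P
  kd_grid <- c(0.1, 1, 10, 100, 1000, stats::median(L[L > 0]))
  best <- NULL
  for (kd0 in kd_grid) {
    f <- fraction_bound(P, L, kd0)
    a <- sum(f * dd) / sum(f^2)
    a <- min(max(a, 1e-9), 10)
    rss <- sum((dd - a * f)^2)
    if (is.null(best) || rss < best$rss) {
      best <- list(kd = kd0, ddmax = a, rss = rss)
    }
  }
  start <- c(kd = best$kd, ddmax = best$ddmax)
  fit <- tryCatch(
    minpack.lm::nls.lm(
      start, lower = c(kd = 1e-9, ddmax = 1e-9),
      upper = c(kd = 1e6, ddmax = 10),
      fn = function(p) dd - model(p),
      control = minpack.lm::nls.lm.control(
        maxiter = 200, ftol = 1e-10, ptol = 1e-10)),
    error = function(e) NULL)
  if (is.null(fit) || !fit$info %in% 1:4) return(out)
  cf <- fit$par
  list(kd = unname(cf["kd"]), ddmax = unname(cf["ddmax"]),
       residual = sum((dd - model(cf))^2), converged = TRUE,
       fitted = unname(model(cf)))
}

#' Aggregate per-residue dissociation constants
#'
#' Single-pass outlier screen: compute the mean and standard deviation of
#' all supplied Kd values, drop values outside mean +/- 2 sd, and report
#' the mean and standard deviation of the retained set. The screen is run
#' once, reflecting that a well-behaved titration yields at most an
#' isolated outlying residue.
#'
#' @param kds numeric vector of per-residue Kd values (uM), at least 3.
#' @param sd_type `"population"` (default) or `"sample"`.
#' @return List with `kd_mean`, `kd_sd`, logical `retained`, and
#'   `first_pass` (mean/sd before screening).
#' @examples
#' aggregate_kd(c(rep(10, 14), 100))
#' @export
aggregate_kd <- function(kds, sd_type = c("population", "sample")) {
  sd_type <- match.arg(sd_type)
  check_finite(kds, "kds")
  if (length(kds) < 3L) {
    stop("need at least 3 converged residue fits", call. = FALSE)
  }
  m1 <- mean(kds)
  s1 <- sd_by_type(kds, sd_type)
  retained <- kds >= m1 - 2 * s1 & kds <= m1 + 2 * s1
  list(kd_mean = mean(kds[retained]),
       kd_sd = sd_by_type(kds[retained], sd_type),
       retained = retained,
       first_pass = list(mean = m1, sd = s1))
}

#' Ratio of two dissociation constants
#'
#' @param kd_a,kd_b dissociation constants (same units), both positive.
#' @return `kd_a / kd_b` — e.g. how many fold weaker `a` binds than `b`.
#' @examples
#' fold_change(180, 12)  # 15-fold weaker
#' @export
fold_change <- function(kd_a, kd_b) {
  check_positive(kd_a, "kd_a")
  check_positive(kd_b, "kd_b")
  kd_a / kd_b
}
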