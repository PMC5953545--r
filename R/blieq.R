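# Sensorgram processing: referencing, baseline alignment, smoothing,
# steady-state response extraction.

sensorgram_rate <- function(gram) {
  dt <- diff(gram$time_s)
  1 / stats::median(dt)
}

check_sensorgram <- function(gram) {
  stopifnot(inherits(gram, "sensorgram"))
  if (is.unsorted(gram$time_s, strictly = TRUE)) {
    stop("sensorgram time must be strictly increasing", call. = FALSE)
  }
  ph <- rle(gram$phase)$values
  want <- c("baseline", "association", "dissociation")
  if (!identical(ph, want[want %in% ph])) {
    stop("phases must be contiguous and ordered baseline -> association -> dissociation",
         call. = FALSE)
  }
  invisible(gram)
}

#' Subtract reference sensorgrams
#'
#' Single referencing subtracts the loaded-sensor-vs-buffer channel from
#' the sample channel, removing sensor drift and baseline offset. Double
#' referencing additionally subtracts the unloaded-sensor-vs-analyte
#' channel, removing analyte bulk/optical artifacts and non-specific
#' binding.
#'
#' @param sample sample `"sensorgram"`.
#' @param loaded_ref loaded-sensor-vs-buffer `"sensorgram"` (role
#'   `reference`).
#' @param unloaded_ref unloaded-sensor-vs-analyte `"sensorgram"` (role
#'   `double_reference`); required for `scheme = "double"`.
#' @param scheme `"single"` or `"double"`.
#' @return The corrected `"sensorgram"` (same time grid as `sample`).
#' @export
subtract_reference <- function(sample, loaded_ref, unloaded_ref = NULL,
                               scheme = c("double", "single")) {
  scheme <- match.arg(scheme)
  check_sensorgram(sample)
  if (missing(loaded_ref) || is.null(loaded_ref)) {
    stop("scheme `", scheme, "` requires a loaded reference channel",
         call. = FALSE)
  }
  check_sensorgram(loaded_ref)
  check_grid <- function(ref) {
    if (nrow(ref) != nrow(sample) ||
        max(abs(ref$time_s - sample$time_s)) >
          1.5 * stats::median(diff(sample$time_s))) {
      stop("reference time grid does not match the sample channel",
           call. = FALSE)
    }
  }
  check_grid(loaded_ref)
  resp <- sample$response - loaded_ref$response
  if (scheme == "double") {
    if (is.null(unloaded_ref)) {
      stop("scheme `double` requires an unloaded analyte reference channel",
           call. = FALSE)
    }
    check_sensorgram(unloaded_ref)
    check_grid(unloaded_ref)
    resp <- resp - unloaded_ref$response
  }
  new_sensorgram(sample$time_s, resp, sample$phase, "sample",
                 attr(sample, "analyte_conc"),
                 paste0(attr(sample, "channel_id"), "_ref"))
}

#' Align a sensorgram to its baseline
#'
#' Subtracts the mean response over the final `window_s` seconds of the
#' baseline phase from the whole trace, so the baseline tail averages
#' zero.
#'
#' @param gram a `"sensorgram"`.
#' @param window_s alignment window in seconds (instrument practice is
#'   5-10 s; default 10).
#' @return The aligned `"sensorgram"`.
#' @export
align_baseline <- function(gram, window_s = 10) {
  check_sensorgram(gram)
  check_positive(window_s, "window_s")
  ib <- which(gram$phase == "baseline")
  if (!length(ib)) stop("sensorgram has no baseline phase", call. = FALSE)
  t_end <- gram$time_s[max(ib)]
  if (t_end - gram$time_s[min(ib)] < window_s) {
    stop("baseline phase is shorter than the alignment window",
         call. = FALSE)
  }
  sel <- ib[gram$time_s[ib] >= t_end - window_s]
  gram$response <- gram$response - mean(gram$response[sel])
  gram
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing. Polynomials of degree at
#' most `order` are reproduced exactly.
#'
#' @param x numeric series, or a `"sensorgram"` (smoothed in place).
#' @param window odd window length in points (default 15, i.e. 1.5 s at
#'   10 Hz).
#' @param order polynomial order, strictly less than `window`.
#' @return Smoothed series (or sensorgram).
#' @export
sg_smooth <- function(x, window = 15, order = 2) {
  if (window %% 2 != 1 || window < 3) {
    stop("`window` must be an odd integer >= 3", call. = FALSE)
  }
  if (order >= window || order < 0) {
    stop("`order` must be non-negative and smaller than `window`",
         call. = FALSE)
  }
  if (inherits(x, "sensorgram")) {
    x$response <- sg_smooth(x$response, window, order)
    return(x)
  }
  check_finite(x, "x")
  if (length(x) < window) {
    stop("series shorter than the smoothing window", call. = FALSE)
  }
  as.numeric(signal::sgolayfilt(x, p = order, n = window))
}

#' Equilibrium (steady-state) response
#'
#' Arithmetic mean of the response over the final `window_s` seconds of
#' the association phase.
#'
#' @param gram a `"sensorgram"`.
#' @param window_s averaging window (s); default 20.
#' @return Equilibrium response `r_eq` (response units).
#' @export
equilibrium_response <- function(gram, window_s = 20) {
  check_sensorgram(gram)
  check_positive(window_s, "window_s")
  ia <- which(gram$phase == "association")
  if (!length(ia)) {
    stop("sensorgram has no association phase", call. = FALSE)
  }
  t_end <- gram$time_s[max(ia)]
  if (t_end - gram$time_s[min(ia)] < window_s) {
    stop("association phase is shorter than the averaging window",
         call. = FALSE)
  }
  sel <- ia[gram$time_s[ia] >= t_end - window_s]
  mean(gram$response[sel])
}

# Plateau check: compare the last association window with the preceding
# one. The difference must be both statistically resolvable (block-based
# standard errors, robust to smoothing-induced autocorrelation) and a
# meaningful fraction of the reached response before a channel is
# flagged as still climbing.
is_plateaued <- function(gram, window_s = 20, tol = 0.02) {
  ia <- which(gram$phase == "association")
  t_end <- gram$time_s[max(ia)]
  last <- ia[gram$time_s[ia] >= t_end - window_s]
  prev <- ia[gram$time_s[ia] >= t_end - 2 * window_s &
               gram$time_s[ia] < t_end - window_s]
  if (length(prev) < 10L) return(TRUE)
  block_se <- function(idx, k = 5L) {
    # noise-only SE of the window mean: block means of the detrended
    # series, so a genuine trend does not inflate the estimate
    y <- gram$response[idx]
    y <- stats::residuals(stats::lm(y ~ seq_along(y)))
    bm <- tapply(y, cut(seq_along(y), k, labels = FALSE), mean)
    stats::sd(bm) / sqrt(k)
  }
  delta <- abs(mean(gram$response[last]) - mean(gram$response[prev]))
  se <- sqrt(block_se(last)^2 + block_se(prev)^2) + 1e-12
  scale <- max(abs(mean(gram$response[last])), 0.02)
  delta < 4 * se || delta < tol * scale
}
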