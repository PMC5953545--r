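#' Specification of a synthetic BLI experiment
#'
#' Describes a 1:1 biolayer-interferometry experiment: a ladder of analyte
#' concentrations, three phases (baseline, association, dissociation)
#' sampled at a fixed rate, and the instrument artifacts that the
#' referencing pipeline is meant to remove. Loaded channels carry a slow
#' linear sensor drift; analyte wells additionally carry a bulk
#' refractive-index offset proportional to analyte concentration, present
#' only while the sensor is dipped in analyte.
#'
#' @param analyte_concs analyte concentrations (uM). The default is the
#'   seven-step ladder used for tail-peptide measurements:
#'   20, 10, 5, 2.5, 1.3, 0.6, 0.3 uM.
#' @param kd_true equilibrium dissociation constant (uM).
#' @param kon association rate constant (1/(uM s)). The default 0.1 is
#'   fast enough that a 300 s association phase plateaus at every ladder
#'   concentration.
#' @param rmax,r0 saturating and baseline response (nm).
#' @param phase_durations named numeric: `baseline`, `association`,
#'   `dissociation` durations in seconds.
#' @param sample_rate sampling rate (Hz).
#' @param drift_rate linear drift on loaded sensors (response/s).
#' @param bulk_per_uM bulk refractive offset per uM analyte (response/uM),
#'   the artifact that double referencing removes.
#' @param noise_sd Gaussian measurement noise s.d. (response units).
#' @param seed integer seed.
#' @return An object of class `"bli_spec"`.
#' @export
bli_spec <- function(analyte_concs = c(20, 10, 5, 2.5, 1.3, 0.6, 0.3),
                     kd_true = 7, kon = 0.1, rmax = 1, r0 = 0,
                     phase_durations = c(baseline = 180, association = 300,
                                         dissociation = 300),
                     sample_rate = 10, drift_rate = 2e-5,
                     bulk_per_uM = 0.002, noise_sd = 0.01, seed = 1L) {
  check_positive(analyte_concs, "analyte_concs")
  check_positive(kd_true, "kd_true")
  check_positive(kon, "kon")
  check_positive(sample_rate, "sample_rate")
  check_positive(phase_durations, "phase_durations")
  stopifnot(length(phase_durations) == 3L)
  names(phase_durations) <- c("baseline", "association", "dissociation")
  check_finite(drift_rate, "drift_rate")
  check_nonneg(noise_sd, "noise_sd")
  structure(
    list(analyte_concs = analyte_concs, kd_true = kd_true, kon = kon,
         rmax = rmax, r0 = r0, phase_durations = phase_durations,
         sample_rate = sample_rate, drift_rate = drift_rate,
         bulk_per_uM = bulk_per_uM, noise_sd = noise_sd,
         seed = as.integer(seed)),
    class = "bli_spec")
}

# Time grid and phase labels for one channel.
bli_time_grid <- function(spec) {
  dt <- 1 / spec$sample_rate
  total <- sum(spec$phase_durations)
  t <- seq(0, total, by = dt)
  phase <- rep("dissociation", length(t))
  phase[t < spec$phase_durations[["baseline"]] +
          spec$phase_durations[["association"]]] <- "association"
  phase[t < spec$phase_durations[["baseline"]]] <- "baseline"
  list(time = t, phase = phase)
}

# Noise-free 1:1 binding response for one concentration on the grid.
bli_binding_curve <- function(spec, conc, grid) {
  koff <- spec$kon * spec$kd_true
  req <- (spec$rmax - spec$r0) * conc / (conc + spec$kd_true)
  t0 <- spec$phase_durations[["baseline"]]
  t1 <- t0 + spec$phase_durations[["association"]]
  r <- numeric(length(grid$time))
  ia <- grid$phase == "association"
  id <- grid$phase == "dissociation"
  kobs <- spec$kon * conc + koff
  r[ia] <- req * (1 - exp(-kobs * (grid$time[ia] - t0)))
  r_end <- req * (1 - exp(-kobs * (t1 - t0)))
  r[id] <- r_end * exp(-koff * (grid$time[id] - t1))
  r
}

new_sensorgram <- function(time, response, phase, role, conc, id) {
  structure(
    data.frame(time_s = time, response = response, phase = phase,
               stringsAsFactors = FALSE),
    role = role, analyte_conc = conc, channel_id = id,
    class = c("sensorgram", "data.frame"))
}

#' Generate synthetic BLI sensorgrams
#'
#' Produces, per analyte concentration, a loaded sample channel and an
#' unloaded analyte reference channel, plus a single loaded
#' buffer-reference channel. Sample channels contain the 1:1 binding
#' signal `Req (1 - exp(-(kon C + koff) t))` in association (with
#' `Req = (rmax - r0) C / (C + Kd)` and `koff = kon Kd`) and a
#' single-exponential decay in dissociation, on top of baseline `r0`,
#' drift, and the bulk offset. Reference channels carry the artifacts but
#' no binding signal.
#'
#' @param spec a [bli_spec()].
#' @return A `"bli_set"`: list of `"sensorgram"` objects with attributes
#'   `role` (`"sample"`, `"reference"`, `"double_reference"`),
#'   `analyte_conc` and `channel_id`.
#' @export
simulate_bli <- function(spec) {
  stopifnot(inherits(spec, "bli_spec"))
  grid <- bli_time_grid(spec)
  nt <- length(grid$time)
  drift <- spec$drift_rate * grid$time
  with_seed(spec$seed, {
    out <- list()
    for (conc in spec$analyte_concs) {
      bulk <- spec$bulk_per_uM * conc * (grid$phase == "association")
      signal <- bli_binding_curve(spec, conc, grid)
      out[[length(out) + 1L]] <- new_sensorgram(
        grid$time, spec$r0 + signal + drift + bulk +
          rnorm(nt, 0, spec$noise_sd),
        grid$phase, "sample", conc, sprintf("sample_%g", conc))
      out[[length(out) + 1L]] <- new_sensorgram(
        grid$time, bulk + rnorm(nt, 0, spec$noise_sd),
        grid$phase, "double_reference", conc, sprintf("unloaded_%g", conc))
    }
    out[[length(out) + 1L]] <- new_sensorgram(
      grid$time, spec$r0 + drift + rnorm(nt, 0, spec$noise_sd),
      grid$phase, "reference", 0, "loaded_buffer")
    structure(out, class = "bli_set", spec_rate = spec$sample_rate)
  })
}

#' @export
print.bli_set <- function(x, ...) {
  roles <- vapply(x, attr, "", "role")
  concs <- vapply(x, attr, 0, "analyte_conc")
  cat(sprintf("BLI sensorgram set: %d channels (%d sample)\n",
              length(x), sum(roles == "sample")))
  cat(sprintf("  analyte ladder: %s uM\n",
              paste(sort(unique(concs[roles == "sample"]),
                         decreasing = TRUE), collapse = ", ")))
  invisible(x)
}

#' Write / read a sensorgram CSV
#'
#' Long format with columns `channel_id`, `role`, `analyte_conc_uM`,
#' `phase`, `time_s`, `response`.
#'
#' @param set a `"bli_set"`.
#' @param path file path.
#' @return `read_sensorgrams()` returns a `"bli_set"`;
#'   `write_sensorgrams()` returns `path` invisibly.
#' @export
write_sensorgrams <- function(set, path) {
  stopifnot(inherits(set, "bli_set"))
  dfs <- lapply(set, function(g) {
    data.frame(channel_id = attr(g, "channel_id"),
               role = attr(g, "role"),
               analyte_conc_uM = attr(g, "analyte_conc"),
               phase = g$phase, time_s = g$time_s, response = g$response,
               stringsAsFactors = FALSE)
  })
  write.csv(do.call(rbind, dfs), path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_sensorgrams
#' @export
read_sensorgrams <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("channel_id", "role", "analyte_conc_uM", "phase", "time_s",
            "response")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("sensorgram CSV is missing column(s): ",
         paste(miss, collapse = ", "), call. = FALSE)
  }
  out <- lapply(split(df, df$channel_id), function(sub) {
    sub <- sub[order(sub$time_s), , drop = FALSE]
    new_sensorgram(sub$time_s, sub$response, sub$phase, sub$role[1],
                   sub$analyte_conc_uM[1], sub$channel_id[1])
  })
  structure(unname(out), class = "bli_set")
}
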