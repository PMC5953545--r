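#' Fraction of protein bound under ligand depletion
#'
#' Single-site binding isotherm valid when the ligand is depleted by
#' binding, i.e. when its concentration is comparable to that of the
#' observed protein. This is the quadratic solution of the 1:1 equilibrium
#' `P + L <-> PL`:
#' \deqn{f = \frac{(L+P+K_d) - \sqrt{(L+P+K_d)^2 - 4PL}}{2P}}
#'
#' @param P protein concentration (uM); strictly positive.
#' @param L total ligand concentration (uM); non-negative.
#' @param Kd dissociation constant (uM); non-negative.
#' @return Bound fraction in `[0, 1]`, vectorized over the inputs.
#'   Always at most `min(L, P) / P`.
#' @examples
#' fraction_bound(50, 250, 12)
#' fraction_bound(50, 25, 0)   # stoichiometric limit: 0.5
#' @export
fraction_bound <- function(P, L, Kd) {
  check_positive(P, "P")
  check_nonneg(L, "L")
  check_nonneg(Kd, "Kd")
  b <- L + P + Kd
  disc <- b^2 - 4 * P * L
  # the discriminant is analytically >= (P - L)^2 + Kd terms >= 0; clamp
  # rounding noise only
  disc[disc < 0] <- 0
  (b - sqrt(disc)) / (2 * P)
}

#' Specification of a synthetic NMR titration
#'
#' Describes a two-state fast-exchange chemical-shift titration with
#' ligand depletion. Observed peak positions interpolate linearly (in the
#' bound fraction) between apo and bound endpoints; the protein
#' concentration may decrease across points to represent dilution by the
#' titrant, which is why both `p_conc` and `l_conc` are carried per point.
#'
#' @param residues character vector of unique residue identifiers.
#' @param apo_shift,bound_shift two-column matrices (`h_ppm`, `n_ppm`) of
#'   per-residue endpoint positions; rows follow `residues`.
#' @param kd_true true dissociation constant (uM).
#' @param points data frame with columns `p_conc` and `l_conc` (uM), one
#'   row per titration point, the first of which must be apo
#'   (`l_conc = 0`).
#' @param noise_sd length-2 numeric: Gaussian noise s.d. in ppm for the
#'   1H and 15N dimensions. Defaults (0.002, 0.013) give both dimensions
#'   roughly equal weight in the composite shift.
#' @param seed integer seed controlling all random draws.
#' @param slow_exchange if `TRUE`, generate two peaks per residue at the
#'   fixed apo and bound positions with complementary intensities
#'   `1 - f` and `f`, instead of a single moving peak.
#' @return An object of class `"titration_spec"`.
#' @seealso [simulate_titration()], [titration_schedule()]
#' @export
titration_spec <- function(residues, apo_shift, bound_shift, kd_true, points,
                           noise_sd = c(0.002, 0.013), seed = 1L,
                           slow_exchange = FALSE) {
  residues <- as.character(residues)
  if (anyDuplicated(residues)) {
    stop("duplicate residue identifiers are not allowed", call. = FALSE)
  }
  apo_shift <- as.matrix(apo_shift)
  bound_shift <- as.matrix(bound_shift)
  stopifnot(nrow(apo_shift) == length(residues),
            nrow(bound_shift) == length(residues),
            ncol(apo_shift) == 2L, ncol(bound_shift) == 2L)
  check_positive(kd_true, "kd_true")
  points <- as.data.frame(points)
  stopifnot(all(c("p_conc", "l_conc") %in% names(points)))
  check_positive(points$p_conc, "points$p_conc")
  check_nonneg(points$l_conc, "points$l_conc")
  if (points$l_conc[1] != 0) {
    stop("the first titration point must be apo (`l_conc = 0`)",
         call. = FALSE)
  }
  check_nonneg(noise_sd, "noise_sd")
  stopifnot(length(noise_sd) == 2L)
  structure(
    list(residues = residues, apo_shift = apo_shift,
         bound_shift = bound_shift, kd_true = kd_true, points = points,
         noise_sd = noise_sd, seed = as.integer(seed),
         slow_exchange = isTRUE(slow_exchange)),
    class = "titration_spec")
}

#' Titration schedule from molar ratios
#'
#' Builds the per-point concentration table for a titration performed at
#' fixed protein concentration and stated protein:ligand molar ratios,
#' optionally applying a dilution factor per added point.
#'
#' @param p0 starting protein concentration (uM).
#' @param ratios ligand:protein molar ratios, starting at 0 (apo).
#' @param dilution multiplicative protein dilution applied cumulatively at
#'   each post-apo point (1 = no dilution).
#' @return data frame with columns `p_conc`, `l_conc`.
#' @examples
#' # the schedule used for tail-peptide titrations at 50 uM protein
#' titration_schedule(50, c(0, 0.1, 0.25, 0.5, 1, 2, 5, 10))
#' @export
titration_schedule <- function(p0, ratios, dilution = 1) {
  check_positive(p0, "p0")
  check_nonneg(ratios, "ratios")
  check_positive(dilution, "dilution")
  if (ratios[1] != 0) stop("`ratios` must start at 0 (apo)", call. = FALSE)
  p <- p0 * dilution^(seq_along(ratios) - 1L)
  data.frame(p_conc = p, l_conc = p * ratios)
}

#' Generate a synthetic titration series
#'
#' Draws per-residue peak positions across titration points from the
#' two-state fast-exchange model: observed shift = apo + f * (bound -
#' apo) + Gaussian noise, with the bound fraction f given by
#' [fraction_bound()] at each point's concentrations. With `noise_sd = 0`
#' the apo point reproduces the apo shifts exactly.
#'
#' @param spec a [titration_spec()].
#' @param missing named list mapping residue identifiers to point indices
#'   at which the peak is unobservable (e.g. broadened); recorded as `NA`.
#' @return A `"titration_series"`: list with `residues`, `h` and `n`
#'   shift matrices (residue x point), `p_conc`, `l_conc`, and (for slow
#'   exchange) `intensity_apo` / `intensity_bound` matrices.
#' @export
simulate_titration <- function(spec, missing = list()) {
  stopifnot(inherits(spec, "titration_spec"))
  nr <- length(spec$residues)
  np <- nrow(spec$points)
  f <- fraction_bound(spec$points$p_conc, spec$points$l_conc, spec$kd_true)
  with_seed(spec$seed, {
    if (spec$slow_exchange) {
      h <- matrix(spec$apo_shift[, 1], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[1]), nr, np)
      n <- matrix(spec$apo_shift[, 2], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[2]), nr, np)
      hb <- matrix(spec$bound_shift[, 1], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[1]), nr, np)
      nb <- matrix(spec$bound_shift[, 2], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[2]), nr, np)
      ia <- matrix(rep(1 - f, each = nr), nr, np)
      ib <- matrix(rep(f, each = nr), nr, np)
      series <- list(residues = spec$residues, h = h, n = n,
                     h_bound = hb, n_bound = nb,
                     intensity_apo = ia, intensity_bound = ib,
                     p_conc = spec$points$p_conc,
                     l_conc = spec$points$l_conc,
                     slow_exchange = TRUE)
    } else {
      fb <- matrix(rep(f, each = nr), nr, np)
      h <- matrix(spec$apo_shift[, 1], nr, np) +
        fb * matrix(spec$bound_shift[, 1] - spec$apo_shift[, 1], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[1]), nr, np)
      n <- matrix(spec$apo_shift[, 2], nr, np) +
        fb * matrix(spec$bound_shift[, 2] - spec$apo_shift[, 2], nr, np) +
        matrix(rnorm(nr * np, 0, spec$noise_sd[2]), nr, np)
      series <- list(residues = spec$residues, h = h, n = n,
                     p_conc = spec$points$p_conc,
                     l_conc = spec$points$l_conc,
                     slow_exchange = FALSE)
    }
    rownames(series$h) <- rownames(series$n) <- spec$residues
    if (length(missing)) {
      bad <- setdiff(names(missing), spec$residues)
      if (length(bad)) {
        stop("`missing` names unknown residues: ",
             paste(bad, collapse = ", "), call. = FALSE)
      }
      for (res in names(missing)) {
        idx <- as.integer(missing[[res]])
        if (any(idx == 1L)) {
          stop("residues cannot be missing at the apo point", call. = FALSE)
        }
        series$h[res, idx] <- NA_real_
        series$n[res, idx] <- NA_real_
      }
    }
    structure(series, class = "titration_series")
  })
}

#' @export
print.titration_series <- function(x, ...) {
  cat(sprintf("Titration series: %d residues, %d points%s\n",
              length(x$residues), length(x$l_conc),
              if (isTRUE(x$slow_exchange)) " (slow exchange)" else ""))
  cat(sprintf("  P: %s uM\n", paste(signif(x$p_conc, 4), collapse = ", ")))
  cat(sprintf("  L: %s uM\n", paste(signif(x$l_conc, 4), collapse = ", ")))
  nmiss <- sum(is.na(x$h))
  if (nmiss) cat(sprintf("  %d unobserved peak(s)\n", nmiss))
  invisible(x)
}

#' Write / read a peak-list CSV
#'
#' Long-format peak list with columns `residue_id`, `residue_name`,
#' `point_index`, `h_ppm`, `n_ppm`, `p_conc_uM`, `l_conc_uM` and an
#' optional `intensity`. Unobserved peaks are omitted from the file and
#' restored as `NA` on reading.
#'
#' @param series a `"titration_series"`.
#' @param path file path.
#' @return `read_peak_list()` returns a `"titration_series"`;
#'   `write_peak_list()` returns `path` invisibly.
#' @export
write_peak_list <- function(series, path) {
  stopifnot(inherits(series, "titration_series"))
  nr <- length(series$residues)
  np <- length(series$l_conc)
  df <- data.frame(
    residue_id = rep(seq_len(nr), np),
    residue_name = rep(series$residues, np),
    point_index = rep(seq_len(np), each = nr),
    h_ppm = as.vector(series$h),
    n_ppm = as.vector(series$n),
    p_conc_uM = rep(series$p_conc, each = nr),
    l_conc_uM = rep(series$l_conc, each = nr))
  df <- df[!is.na(df$h_ppm), , drop = FALSE]
  write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_peak_list
#' @export
read_peak_list <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("residue_name", "point_index", "h_ppm", "n_ppm",
            "p_conc_uM", "l_conc_uM")
  miss <- setdiff(need, names(df))
  if (length(miss)) {
    stop("peak list is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  pts <- sort(unique(df$point_index))
  res <- unique(df$residue_name)
  h <- matrix(NA_real_, length(res), length(pts),
              dimnames = list(res, NULL))
  n <- h
  p_conc <- l_conc <- rep(NA_real_, length(pts))
  for (k in seq_along(pts)) {
    sub <- df[df$point_index == pts[k], , drop = FALSE]
    h[sub$residue_name, k] <- sub$h_ppm
    n[sub$residue_name, k] <- sub$n_ppm
    p_conc[k] <- sub$p_conc_uM[1]
    l_conc[k] <- sub$l_conc_uM[1]
  }
  structure(list(residues = res, h = h, n = n, p_conc = p_conc,
                 l_conc = l_conc, slow_exchange = FALSE),
            class = "titration_series")
}
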