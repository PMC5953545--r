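#' Solvent-accessible surface area (Shrake-Rupley)
#'
#' Per-atom accessible area from the fraction of points on the
#' probe-expanded sphere of each atom that are not buried inside any
#' other atom's probe-expanded sphere. Points are distributed with a
#' golden-spiral lattice. Occlusion is tested against *all* atoms in the
#' structure; the selection only controls which atoms are summed.
#'
#' @param traj a `"trajectory"` (frame 1 unless `frame` is given); all
#'   atoms need radii.
#' @param sel atoms to report (default all).
#' @param probe probe radius in Angstrom (water: 1.4).
#' @param n_points sphere points per atom (default 960).
#' @param frame frame index.
#' @return List with `total` (A^2 over the selection), `per_residue`
#'   (data frame `chain`, `resid`, `area`), and `per_atom` vector.
#' @examples
#' top <- data.frame(chain = "A", resid = 1, resname = "X", name = "C",
#'                   element = "C", mass = 12, charge = 0, radius = 1.9)
#' sasa(trajectory(top, matrix(0, 1, 3)))$total  # 4*pi*(1.9+1.4)^2
#' @export
sasa <- function(traj, sel = NULL, probe = 1.4, n_points = 960L,
                 frame = 1L) {
  stopifnot(inherits(traj, "trajectory"))
  check_nonneg(probe, "probe")
  stopifnot(n_points >= 12L)
  top <- traj$topology
  if (anyNA(top$radius)) {
    stop("all atoms need a radius for SASA", call. = FALSE)
  }
  xyz <- as_frame(traj, frame)
  idx <- if (is.null(sel)) seq_len(nrow(top)) else
    resolve_selection(top, sel)
  pts <- golden_spiral_points(n_points)
  rr <- top$radius + probe
  natom <- nrow(top)
  per_atom <- numeric(natom)
  for (i in idx) {
    ri <- rr[i]
    sphere <- pts * ri + matrix(xyz[i, ], n_points, 3L, byrow = TRUE)
    # neighbours whose expanded spheres can reach this one
    d2 <- rowSums((xyz - matrix(xyz[i, ], natom, 3L, byrow = TRUE))^2)
    nb <- which(d2 < (ri + rr)^2 & seq_len(natom) != i)
    exposed <- rep(TRUE, n_points)
    for (j in nb) {
      if (!any(exposed)) break
      dj2 <- rowSums((sphere[exposed, , drop = FALSE] -
                        matrix(xyz[j, ], sum(exposed), 3L,
                               byrow = TRUE))^2)
      exposed[exposed] <- dj2 > rr[j]^2
    }
    per_atom[i] <- 4 * pi * ri^2 * sum(exposed) / n_points
  }
  key <- paste(top$chain, top$resid)[idx]
  agg <- tapply(per_atom[idx], key, sum)
  pr <- data.frame(
    chain = sub(" .*", "", names(agg)),
    resid = as.integer(sub(".* ", "", names(agg))),
    area = as.numeric(agg), stringsAsFactors = FALSE)
  pr <- pr[order(pr$chain, pr$resid), , drop = FALSE]
  rownames(pr) <- NULL
  list(total = sum(per_atom[idx]), per_residue = pr,
       per_atom = per_atom[idx])
}

# Near-uniform points on the unit sphere (golden-section spiral).
golden_spiral_points <- function(n) {
  k <- seq_len(n) - 0.5
  phi <- acos(1 - 2 * k / n)
  theta <- pi * (1 + sqrt(5)) * k
  cbind(sin(phi) * cos(theta), sin(phi) * sin(theta), cos(phi))
}
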