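# Ideal-geometry backbone construction (internal -> Cartesian, NeRF
# placement). Bond lengths/angles are fixed at standard peptide values;
# only the (phi, psi) dihedrals vary.

BB_GEOM <- list(
  b_n_ca = 1.458, b_ca_c = 1.525, b_c_n = 1.329, b_c_o = 1.231,
  a_n_ca_c = 111.0, a_ca_c_n = 116.6, a_c_n_ca = 121.9, a_ca_c_o = 120.5,
  omega = 180)

deg2rad <- function(x) x * pi / 180

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

unit3 <- function(v) v / sqrt(sum(v^2))

# Place atom D from A-B-C with bond r = |C-D|, angle theta = B-C-D and
# dihedral tau = A-B-C-D (degrees).
place_atom <- function(a, b, c, r, theta, tau) {
  theta <- deg2rad(theta)
  tau <- deg2rad(tau)
  bc <- unit3(c - b)
  n <- unit3(cross3(b - a, bc))
  m <- cross3(n, bc)
  d <- c(-r * cos(theta), r * sin(theta) * cos(tau),
         r * sin(theta) * sin(tau))
  c + d[1] * bc + d[2] * m + d[3] * n
}

# Dihedral angle p1-p2-p3-p4 in degrees, in (-180, 180].
torsion_angle <- function(p1, p2, p3, p4) {
  b1 <- p2 - p1
  b2 <- p3 - p2
  b3 <- p4 - p3
  n1 <- cross3(b1, b2)
  n2 <- cross3(b2, b3)
  m <- cross3(unit3(b2), n1)
  ang <- atan2(sum(m * n2), sum(n1 * n2)) * 180 / pi
  if (ang <= -180) ang <- ang + 360
  ang
}

#' Build an ideal-geometry peptide backbone
#'
#' Constructs Cartesian N/CA/C/O coordinates for a polypeptide backbone
#' from per-residue (phi, psi) dihedrals, using fixed ideal bond lengths
#' (N-CA 1.458, CA-C 1.525, C-N 1.329 A) and angles, with a planar trans
#' peptide bond (omega = 180 deg). `phi[1]` and the carbonyl placement of
#' the final residue use the stated values but do not affect connectivity.
#'
#' @param phi,psi per-residue backbone dihedrals in degrees, each in
#'   `(-180, 180]`; equal length, at least 2 residues.
#' @param chain chain identifier for the emitted topology.
#' @return A `"trajectory"` with a single frame: backbone topology
#'   (4 atoms per residue) and coordinates.
#' @examples
#' helix <- build_backbone(rep(-57, 15), rep(-47, 15))
#' @export
build_backbone <- function(phi, psi, chain = "A") {
  check_finite(phi, "phi")
  check_finite(psi, "psi")
  if (length(phi) != length(psi)) {
    stop("`phi` and `psi` must have equal length", call. = FALSE)
  }
  if (any(phi <= -180 | phi > 180) || any(psi <= -180 | psi > 180)) {
    stop("dihedrals must lie in (-180, 180] degrees", call. = FALSE)
  }
  nres <- length(phi)
  if (nres < 2L) stop("at least 2 residues are required", call. = FALSE)
  g <- BB_GEOM
  xyz <- matrix(NA_real_, nres * 4L, 3L)
  idx <- function(i, atom) (i - 1L) * 4L +
    match(atom, c("N", "CA", "C", "O"))
  # residue 1 in a canonical frame
  xyz[idx(1, "N"), ] <- c(0, 0, 0)
  xyz[idx(1, "CA"), ] <- c(g$b_n_ca, 0, 0)
  th <- deg2rad(180 - g$a_n_ca_c)
  xyz[idx(1, "C"), ] <- xyz[idx(1, "CA"), ] +
    g$b_ca_c * c(cos(th), sin(th), 0)
  for (i in seq_len(nres)) {
    if (i > 1L) {
      xyz[idx(i, "N"), ] <- place_atom(
        xyz[idx(i - 1L, "N"), ], xyz[idx(i - 1L, "CA"), ],
        xyz[idx(i - 1L, "C"), ], g$b_c_n, g$a_ca_c_n, psi[i - 1L])
      xyz[idx(i, "CA"), ] <- place_atom(
        xyz[idx(i - 1L, "CA"), ], xyz[idx(i - 1L, "C"), ],
        xyz[idx(i, "N"), ], g$b_n_ca, g$a_c_n_ca, g$omega)
      xyz[idx(i, "C"), ] <- place_atom(
        xyz[idx(i - 1L, "C"), ], xyz[idx(i, "N"), ],
        xyz[idx(i, "CA"), ], g$b_ca_c, g$a_n_ca_c, phi[i])
    }
    # carbonyl O in the peptide plane, anti to the next amide N
    xyz[idx(i, "O"), ] <- place_atom(
      xyz[idx(i, "N"), ], xyz[idx(i, "CA"), ], xyz[idx(i, "C"), ],
      g$b_c_o, g$a_ca_c_o, psi[i] + 180)
  }
  top <- data.frame(
    chain = chain,
    resid = rep(seq_len(nres), each = 4L),
    resname = "ALA",
    name = rep(c("N", "CA", "C", "O"), nres),
    element = rep(c("N", "C", "C", "O"), nres),
    mass = rep(c(14.007, 12.011, 12.011, 15.999), nres),
    charge = 0,
    radius = rep(c(1.55, 1.70, 1.70, 1.52), nres),
    stringsAsFactors = FALSE)
  trajectory(top, array(xyz, dim = c(nrow(xyz), 3L, 1L)))
}

#' Measure backbone dihedrals
#'
#' Recomputes per-residue (phi, psi) from backbone coordinates; the
#' inverse of [build_backbone()] up to numerical precision. `phi` of the
#' first and `psi` of the last residue are `NA` when the flanking atoms
#' do not exist (for constructed backbones `psi` of the last residue is
#' recovered from the carbonyl O placement).
#'
#' @param traj a single-frame `"trajectory"` containing backbone
#'   N/CA/C/O atoms, or anything accepted by [as_frame()].
#' @param chain chain to measure.
#' @return data frame with columns `resid`, `phi`, `psi`.
#' @export
backbone_dihedrals <- function(traj, chain = NULL) {
  top <- traj$topology
  xyz <- as_frame(traj, 1L)
  if (!is.null(chain)) {
    keep <- top$chain == chain
    xyz <- xyz[keep, , drop = FALSE]
    top <- top[keep, , drop = FALSE]
  }
  resids <- unique(top$resid)
  get <- function(i, atom) {
    j <- which(top$resid == resids[i] & top$name == atom)
    if (length(j) != 1L) return(NULL)
    xyz[j, ]
  }
  n <- length(resids)
  phi <- psi <- rep(NA_real_, n)
  for (i in seq_len(n)) {
    if (i > 1L) {
      phi[i] <- torsion_angle(get(i - 1L, "C"), get(i, "N"),
                              get(i, "CA"), get(i, "C"))
    }
    if (i < n) {
      psi[i] <- torsion_angle(get(i, "N"), get(i, "CA"), get(i, "C"),
                              get(i + 1L, "N"))
    } else {
      o <- get(i, "O")
      if (!is.null(o)) {
        a <- torsion_angle(get(i, "N"), get(i, "CA"), get(i, "C"), o) - 180
        if (a <= -180) a <- a + 360
        psi[i] <- a
      }
    }
  }
  data.frame(resid = resids, phi = phi, psi = psi)
}
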