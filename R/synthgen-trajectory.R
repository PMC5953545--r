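#' Specification of a synthetic tail/DNA trajectory ensemble
#'
#' Describes an ensemble of conformations of a flexible, charged bead
#' chain (a coarse histone tail, one bead per residue) near a fixed
#' cylindrical array of negatively charged pseudo-phosphate sites (a
#' coarse DNA surface). Each frame is an independent draw: a fresh
#' self-avoiding chain is relaxed by Metropolis resampling (crankshaft
#' and end-pivot bead moves plus whole-chain translations) with
#' acceptance `exp(-collapse * dE / kT)`, where `dE` is the change in
#' screened tail-DNA Coulomb energy. `collapse = 0` therefore yields an
#' unbiased confined ensemble and `collapse = 1` the strongest surface
#' bias. This is an ensemble generator, not dynamics: only
#' distributional properties are meaningful.
#'
#' @param n_frames number of frames (independent conformations).
#' @param n_tail_residues beads per tail chain.
#' @param collapse surface-bias strength in `[0, 1]`.
#' @param dna_atoms number of pseudo-phosphate sites (charge -1 each).
#' @param tail_charges per-bead signed charges (e). The default mixes
#'   arginine-like (+1.5), lysine-like (+1.0) and neutral beads in an
#'   H3-tail-like pattern.
#' @param n_tails 1 or 2 tail chains (chains "A" and "B").
#' @param n_sweeps Metropolis sweeps per frame.
#' @param seed integer seed.
#' @return An object of class `"traj_spec"`.
#' @export
traj_spec <- function(n_frames, n_tail_residues = 10, collapse = 0.5,
                      dna_atoms = 60,
                      tail_charges = NULL,
                      n_tails = 1L, n_sweeps = 150L, seed = 1L) {
  if (is.null(tail_charges)) {
    base <- c(1, 1.5, 0, 1, 0, 0, 1.5, 1, 1, 1.5)
    tail_charges <- rep_len(base, n_tail_residues)
  }
  check_finite(tail_charges, "tail_charges")
  stopifnot(length(tail_charges) == n_tail_residues)
  if (!is.numeric(collapse) || length(collapse) != 1L ||
      collapse < 0 || collapse > 1) {
    stop("`collapse` must be a single value in [0, 1]", call. = FALSE)
  }
  if (n_frames < 1L) stop("`n_frames` must be >= 1", call. = FALSE)
  stopifnot(n_tails %in% c(1L, 2L), n_sweeps >= 1L, dna_atoms >= 1L,
            n_tail_residues >= 3L)
  structure(
    list(n_frames = as.integer(n_frames),
         n_tail_residues = as.integer(n_tail_residues),
         collapse = collapse, dna_atoms = as.integer(dna_atoms),
         tail_charges = tail_charges, n_tails = as.integer(n_tails),
         n_sweeps = as.integer(n_sweeps), seed = as.integer(seed)),
    class = "traj_spec")
}

# Fixed pseudo-DNA geometry: sites on a helix wound on a cylinder of
# radius 10 A spanning 40 A along z.
pseudo_dna_sites <- function(n) {
  zlen <- 40
  radius <- 10
  t <- seq(0, 4 * pi, length.out = n)
  cbind(radius * cos(t), radius * sin(t),
        seq(-zlen / 2, zlen / 2, length.out = n))
}

TAIL_BOND <- 3.8    # A, bead-bead bond length
TAIL_RADIUS <- 1.9  # A, hard-sphere bead radius
DNA_RADIUS <- 2.0   # A, pseudo-phosphate site radius
KT_KCAL <- 0.593    # kcal/mol at 298 K
BOX_R <- 35         # A, confinement cylinder radius
BOX_Z <- 22         # A, confinement half-height

inside_box <- function(p) {
  all(p[, 1]^2 + p[, 2]^2 <= BOX_R^2) && all(abs(p[, 3]) <= BOX_Z)
}

# squared distances of one point to all rows of m
dist2_to <- function(m, p) {
  rowSums(m^2) + sum(p^2) - 2 * as.vector(m %*% p)
}

clash_free <- function(pos, b, cand, dna) {
  # bonded neighbours are exempt from the hard-sphere check
  others <- pos[setdiff(seq_len(nrow(pos)), c(b - 1L, b, b + 1L)), ,
                drop = FALSE]
  if (nrow(others) && min(dist2_to(others, cand)) < (2 * TAIL_RADIUS)^2) {
    return(FALSE)
  }
  min(dist2_to(dna, cand)) >= (TAIL_RADIUS + DNA_RADIUS)^2
}

# One self-avoiding chain of `n` beads anchored in an annulus around
# the DNA cylinder; returns n x 3 matrix.
sample_chain <- function(n, dna, anchor_shift = 0) {
  for (attempt in seq_len(60L)) {
    r <- runif(1, 14, 30)
    ang <- runif(1, 0, 2 * pi) + anchor_shift
    pos <- matrix(NA_real_, n, 3L)
    pos[1L, ] <- c(r * cos(ang), r * sin(ang), runif(1, -12, 12))
    ok <- TRUE
    for (b in 2L:n) {
      placed <- FALSE
      for (try in seq_len(120L)) {
        v <- rnorm(3)
        cand <- pos[b - 1L, ] + TAIL_BOND * v / sqrt(sum(v^2))
        if (b > 2L) {
          prior <- pos[seq_len(b - 2L), , drop = FALSE]
          if (min(dist2_to(prior, cand)) < (2 * TAIL_RADIUS)^2) next
        }
        if (min(dist2_to(dna, cand)) < (TAIL_RADIUS + DNA_RADIUS)^2) next
        if (cand[1]^2 + cand[2]^2 > BOX_R^2 || abs(cand[3]) > BOX_Z) next
        pos[b, ] <- cand
        placed <- TRUE
        break
      }
      if (!placed) { ok <- FALSE; break }
    }
    if (ok) return(pos)
  }
  stop("failed to generate a self-avoiding chain", call. = FALSE)
}

# Screened (eps = 4r) Coulomb energy of one bead against the DNA sites.
bead_dna_energy <- function(p, q, dna) {
  if (q == 0) return(0)
  sum(332.0636 * q * (-1) / (4 * dist2_to(dna, p)))
}

chain_dna_energy <- function(pos, charges, dna) {
  sum(vapply(seq_len(nrow(pos)), function(b)
    bead_dna_energy(pos[b, ], charges[b], dna), numeric(1)))
}

# rotation matrix about unit axis u by angle a (Rodrigues)
rot_about <- function(u, a) {
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  diag(3) + sin(a) * K + (1 - cos(a)) * (K %*% K)
}

# Metropolis relaxation of one chain; mutates and returns `pos`.
relax_chain <- function(pos, charges, dna, collapse, n_sweeps) {
  n <- nrow(pos)
  for (sw in seq_len(n_sweeps)) {
    for (b in seq_len(n)) {
      a <- runif(1, -pi, pi)
      if (b == 1L || b == n) {
        piv <- if (b == 1L) pos[2L, ] else pos[n - 1L, ]
        ax <- rnorm(3)
        ax <- ax / sqrt(sum(ax^2))
        cand <- as.vector(rot_about(ax, a) %*% (pos[b, ] - piv)) + piv
      } else {
        ax <- pos[b + 1L, ] - pos[b - 1L, ]
        nrm <- sqrt(sum(ax^2))
        if (nrm < 1e-9) next
        cand <- as.vector(rot_about(ax / nrm, a) %*%
                            (pos[b, ] - pos[b - 1L, ])) + pos[b - 1L, ]
      }
      if (cand[1]^2 + cand[2]^2 > BOX_R^2 || abs(cand[3]) > BOX_Z) next
      if (!clash_free(pos, b, cand, dna)) next
      de <- bead_dna_energy(cand, charges[b], dna) -
        bead_dna_energy(pos[b, ], charges[b], dna)
      if (runif(1) < exp(-collapse * de / KT_KCAL)) pos[b, ] <- cand
    }
    # whole-chain translation
    shift <- rnorm(3, 0, 1.5)
    cand <- pos + matrix(shift, n, 3L, byrow = TRUE)
    if (inside_box(cand) &&
        min(vapply(seq_len(n), function(b)
          min(dist2_to(dna, cand[b, ])), numeric(1))) >=
          (TAIL_RADIUS + DNA_RADIUS)^2) {
      de <- chain_dna_energy(cand, charges, dna) -
        chain_dna_energy(pos, charges, dna)
      if (runif(1) < exp(-collapse * de / KT_KCAL)) pos <- cand
    }
  }
  pos
}

#' Generate a synthetic tail/DNA trajectory ensemble
#'
#' See [traj_spec()] for the model. Deterministic given `(spec, seed)`;
#' with `collapse = 0`, or with all tail charges zero, every Metropolis
#' move is accepted and — for the same seed — the unbiased ensemble is
#' reproduced draw for draw.
#'
#' @param spec a [traj_spec()].
#' @return A `"trajectory"` whose topology tags the DNA sites as chain
#'   `"D"` (residue name `DNA`) and tail beads as chains `"A"` (and
#'   `"B"`), with per-bead charges and radii.
#' @export
simulate_tail_trajectory <- function(spec) {
  stopifnot(inherits(spec, "traj_spec"))
  dna <- pseudo_dna_sites(spec$dna_atoms)
  nb <- spec$n_tail_residues
  chains <- c("A", "B")[seq_len(spec$n_tails)]
  natoms <- spec$dna_atoms + nb * spec$n_tails
  coords <- array(NA_real_, dim = c(natoms, 3L, spec$n_frames))
  with_seed(spec$seed, {
    for (fr in seq_len(spec$n_frames)) {
      coords[seq_len(spec$dna_atoms), , fr] <- dna
      off <- spec$dna_atoms
      for (ch in seq_along(chains)) {
        pos <- sample_chain(nb, dna, anchor_shift = (ch - 1) * pi)
        pos <- relax_chain(pos, spec$tail_charges, dna, spec$collapse,
                           spec$n_sweeps)
        coords[off + seq_len(nb), , fr] <- pos
        off <- off + nb
      }
    }
  })
  top <- data.frame(
    chain = c(rep("D", spec$dna_atoms), rep(chains, each = nb)),
    resid = c(seq_len(spec$dna_atoms), rep(seq_len(nb), spec$n_tails)),
    resname = c(rep("DNA", spec$dna_atoms),
                rep("TLB", nb * spec$n_tails)),
    name = c(rep("P", spec$dna_atoms), rep("CB", nb * spec$n_tails)),
    element = c(rep("P", spec$dna_atoms), rep("C", nb * spec$n_tails)),
    mass = c(rep(94.97, spec$dna_atoms), rep(100, nb * spec$n_tails)),
    charge = c(rep(-1, spec$dna_atoms),
               rep(spec$tail_charges, spec$n_tails)),
    radius = c(rep(DNA_RADIUS, spec$dna_atoms),
               rep(TAIL_RADIUS, nb * spec$n_tails)),
    stringsAsFactors = FALSE)
  out <- trajectory(top, coords)
  out$spec <- spec
  out
}

#' Minimum tail-DNA distance per frame
#'
#' @param traj a `"trajectory"` with a `"D"` (DNA) chain.
#' @param tail_chain tail chain identifier.
#' @return Numeric vector, one minimum bead-site distance per frame.
#' @export
tail_dna_distance <- function(traj, tail_chain = "A") {
  stopifnot(inherits(traj, "trajectory"))
  id <- which(traj$topology$chain == "D")
  it <- which(traj$topology$chain == tail_chain)
  if (!length(id) || !length(it)) {
    stop("trajectory must contain a DNA chain `D` and the tail chain",
         call. = FALSE)
  }
  vapply(seq_len(n_frames(traj)), function(fr) {
    xyz <- as_frame(traj, fr)
    sqrt(min(vapply(it, function(b)
      min(dist2_to(xyz[id, , drop = FALSE], xyz[b, ])), numeric(1))))
  }, numeric(1))
}
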