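# Trajectory I/O. Multi-model PDB read/write goes through bio3d; DCD
# reading uses bio3d::read.dcd, and a minimal CHARMM-format DCD writer
# is provided because bio3d has no write counterpart.
#
# Convention for topology round trips through PDB: the occupancy column
# stores the partial charge and the B-factor column the atomic radius.

ELEMENT_MASS <- c(H = 1.008, C = 12.011, N = 14.007, O = 15.999,
                  P = 30.974, S = 32.06, ZN = 65.38)

element_mass <- function(element) {
  m <- ELEMENT_MASS[toupper(element)]
  m[is.na(m)] <- 12.011
  unname(m)
}

#' Write / read a trajectory as multi-model PDB
#'
#' One MODEL per frame. Partial charges are stored in the occupancy
#' column and radii in the B-factor column (a documented repurposing, so
#' a topology can round-trip through the text format).
#'
#' @param traj a `"trajectory"`.
#' @param path file path.
#' @return `read_trajectory_pdb()` returns a `"trajectory"`;
#'   `write_trajectory_pdb()` returns `path` invisibly.
#' @export
write_trajectory_pdb <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  nfr <- n_frames(traj)
  xyz <- t(vapply(seq_len(nfr), function(fr) {
    as.vector(t(as_frame(traj, fr)))
  }, numeric(3L * nrow(top))))
  if (nfr == 1L) xyz <- matrix(xyz, nrow = 1L)
  bio3d::write.pdb(file = path, xyz = xyz,
                   resno = top$resid, resid = top$resname,
                   eleno = seq_len(nrow(top)), elety = top$name,
                   chain = top$chain, o = top$charge, b = top$radius,
                   elesy = top$element)
  invisible(path)
}

#' @rdname write_trajectory_pdb
#' @export
read_trajectory_pdb <- function(path) {
  p <- bio3d::read.pdb(path, multi = TRUE, verbose = FALSE)
  at <- p$atom
  top <- data.frame(
    chain = at$chain, resid = at$resno, resname = at$resid,
    name = at$elety,
    element = ifelse(is.na(at$elesy) | at$elesy == "",
                     substr(at$elety, 1L, 1L), at$elesy),
    mass = NA_real_, charge = at$o, radius = at$b,
    stringsAsFactors = FALSE)
  top$mass <- element_mass(top$element)
  nfr <- nrow(p$xyz)
  natom <- nrow(top)
  coords <- array(NA_real_, dim = c(natom, 3L, nfr))
  for (fr in seq_len(nfr)) {
    coords[, , fr] <- matrix(p$xyz[fr, ], natom, 3L, byrow = TRUE)
  }
  trajectory(top, coords)
}

#' Write / read trajectory coordinates as DCD
#'
#' CHARMM-format binary DCD holding coordinates only; the topology
#' travels separately (e.g. via [write_trajectory_pdb()]). Coordinates
#' are stored in single precision, the format's native width.
#'
#' @param traj a `"trajectory"` (writer) .
#' @param path file path.
#' @param topology atom table to pair with the coordinates (reader).
#' @return `read_trajectory_dcd()` returns a `"trajectory"`;
#'   `write_trajectory_dcd()` returns `path` invisibly.
#' @export
write_trajectory_dcd <- function(traj, path) {
  stopifnot(inherits(traj, "trajectory"))
  nfr <- n_frames(traj)
  natom <- nrow(traj$topology)
  con <- file(path, "wb")
  on.exit(close(con))
  rec <- function(writer) {
    # Fortran unformatted record: payload length framing both sides
    raw <- writer()
    writeBin(length(raw), con, size = 4L)
    writeBin(raw, con)
    writeBin(length(raw), con, size = 4L)
  }
  hdr <- function() {
    r <- charToRaw("CORD")
    icntrl <- integer(20L)
    icntrl[1] <- nfr
    icntrl[2] <- 1L   # first step
    icntrl[3] <- 1L   # save frequency
    icntrl[4] <- nfr
    icntrl[20] <- 24L # CHARMM version stamp
    c(r, writeBin(icntrl, raw(), size = 4L))
  }
  rec(hdr)
  rec(function() {
    title <- sprintf("%-80s", "tailscape trajectory")
    c(writeBin(1L, raw(), size = 4L), charToRaw(title))
  })
  rec(function() writeBin(as.integer(natom), raw(), size = 4L))
  for (fr in seq_len(nfr)) {
    xyz <- as_frame(traj, fr)
    for (d in 1:3) {
      rec(function() writeBin(as.numeric(xyz[, d]), raw(), size = 4L))
    }
  }
  invisible(path)
}

#' @rdname write_trajectory_dcd
#' @export
read_trajectory_dcd <- function(path, topology) {
  xyz <- bio3d::read.dcd(path, verbose = FALSE)
  natom <- ncol(xyz) / 3L
  stopifnot(natom == nrow(topology))
  coords <- array(NA_real_, dim = c(natom, 3L, nrow(xyz)))
  for (fr in seq_len(nrow(xyz))) {
    coords[, , fr] <- matrix(xyz[fr, ], natom, 3L, byrow = TRUE)
  }
  trajectory(topology, coords)
}
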