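#' Radius of gyration
#'
#' Mass-weighted RMS distance of the selected atoms from their centre of
#' mass: `sqrt(sum(m_i |r_i - r_com|^2) / sum(m_i))`.
#'
#' @param traj a `"trajectory"` (all frames) or an `n_atoms x 3` frame
#'   matrix.
#' @param sel atom selection (indices, logical mask, or selection
#'   string); default all atoms.
#' @param mass_weighted use topology masses (`TRUE`, default) or unit
#'   masses. A bare frame matrix implies unit masses.
#' @return Rg in Angstrom; one value per frame for a trajectory.
#' @examples
#' radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0)))  # 1.0
#' @export
radius_of_gyration <- function(traj, sel = NULL, mass_weighted = TRUE) {
  if (is.matrix(traj)) {
    xyz <- traj
    idx <- if (is.null(sel)) seq_len(nrow(xyz)) else sel
    m <- rep(1, length(idx))
    return(rg_one(xyz[idx, , drop = FALSE], m))
  }
  stopifnot(inherits(traj, "trajectory"))
  idx <- if (is.null(sel)) seq_len(nrow(traj$topology)) else
    resolve_selection(traj$topology, sel)
  m <- if (mass_weighted) traj$topology$mass[idx] else rep(1, length(idx))
  vapply(seq_len(n_frames(traj)), function(fr) {
    rg_one(as_frame(traj, fr)[idx, , drop = FALSE], m)
  }, numeric(1))
}

rg_one <- function(xyz, m) {
  if (!nrow(xyz)) stop("empty selection", call. = FALSE)
  com <- colSums(xyz * m) / sum(m)
  sqrt(sum(m * rowSums((xyz - matrix(com, nrow(xyz), 3L,
                                     byrow = TRUE))^2)) / sum(m))
}

# Kabsch superposition: proper rotation (det = +1) and translation
# minimising the RMSD of `mobile` onto `ref` (both n x 3).
kabsch_transform <- function(mobile, ref) {
  stopifnot(nrow(mobile) == nrow(ref))
  cm <- colMeans(mobile)
  cr <- colMeans(ref)
  a <- sweep(mobile, 2L, cm)
  b <- sweep(ref, 2L, cr)
  h <- crossprod(a, b)
  s <- svd(h)
  d <- sign(det(s$v %*% t(s$u)))
  rot <- s$v %*% diag(c(1, 1, d)) %*% t(s$u)
  list(rotation = rot, center_mobile = cm, center_ref = cr)
}

apply_transform <- function(xyz, tr) {
  sweep(sweep(xyz, 2L, tr$center_mobile) %*% t(tr$rotation), 2L,
        -tr$center_ref)
}

#' Superposition RMSD with separate fit and measurement selections
#'
#' Finds the optimal rigid-body superposition (Kabsch algorithm, proper
#' rotation enforced) of the mobile frame onto the reference using the
#' `fit_sel` atoms, then evaluates the RMSD over the `rmsd_sel` atoms in
#' the fitted frame. This separates "align on the rigid core" from
#' "measure the flexible tail".
#'
#' @param mobile,ref `n_atoms x 3` frame matrices, or `"trajectory"`
#'   objects (first frame used) with matching atom order.
#' @param fit_sel,rmsd_sel selections (indices/logical/string resolved
#'   against `topology` if supplied, otherwise indices); default all
#'   atoms for both.
#' @param topology optional atom table for string selections.
#' @return RMSD in Angstrom.
#' @export
kabsch_rmsd <- function(mobile, ref, fit_sel = NULL, rmsd_sel = NULL,
                        topology = NULL) {
  if (inherits(mobile, "trajectory")) {
    topology <- topology %||% mobile$topology
    mobile <- as_frame(mobile, 1L)
  }
  if (inherits(ref, "trajectory")) ref <- as_frame(ref, 1L)
  if (!identical(dim(mobile), dim(ref))) {
    stop("mobile and reference frames must have matching atom counts",
         call. = FALSE)
  }
  res <- function(sel) {
    if (is.null(sel)) return(seq_len(nrow(mobile)))
    if (is.character(sel)) {
      if (is.null(topology)) {
        stop("string selections need a `topology`", call. = FALSE)
      }
      return(select_atoms(topology, sel))
    }
    if (is.logical(sel)) which(sel) else as.integer(sel)
  }
  fi <- res(fit_sel)
  ri <- res(rmsd_sel)
  tr <- kabsch_transform(mobile[fi, , drop = FALSE],
                         ref[fi, , drop = FALSE])
  moved <- apply_transform(mobile[ri, , drop = FALSE], tr)
  sqrt(mean(rowSums((moved - ref[ri, , drop = FALSE])^2)))
}

#' Mean pairwise end-state RMSD
#'
#' All-pairs [kabsch_rmsd()] between final-frame conformations of a set
#' of runs: each pair is core-fitted on `fit_sel` and measured on
#' `rmsd_sel`, and the mean over the strict upper triangle is reported.
#' With a `groups` factor, per-group means over within-group pairs are
#' reported as well (e.g. runs started from the same initial
#' conformation).
#'
#' @param frames list of `n_atoms x 3` matrices (matching atom order), at
#'   least 2.
#' @param fit_sel,rmsd_sel,topology as in [kabsch_rmsd()].
#' @param groups optional grouping factor, one value per frame.
#' @return List with `mean`, the full symmetric `matrix`, and
#'   `group_means` (or `NULL`).
#' @export
end_state_rmsd <- function(frames, fit_sel = NULL, rmsd_sel = NULL,
                           topology = NULL, groups = NULL) {
  frames <- lapply(frames, function(f)
    if (inherits(f, "trajectory")) as_frame(f, n_frames(f)) else f)
  n <- length(frames)
  if (n < 2L) stop("need at least 2 frames", call. = FALSE)
  m <- matrix(0, n, n)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      m[i, j] <- m[j, i] <- kabsch_rmsd(frames[[i]], frames[[j]],
                                        fit_sel, rmsd_sel, topology)
    }
  }
  out <- list(mean = mean(m[upper.tri(m)]), matrix = m,
              group_means = NULL)
  if (!is.null(groups)) {
    stopifnot(length(groups) == n)
    gm <- vapply(split(seq_len(n), groups), function(idx) {
      if (length(idx) < 2L) return(NA_real_)
      sub <- m[idx, idx, drop = FALSE]
      mean(sub[upper.tri(sub)])
    }, numeric(1))
    out$group_means <- gm
  }
  out
}
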