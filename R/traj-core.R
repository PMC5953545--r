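#' Trajectory container
#'
#' A minimal container pairing an atom table (topology) with a coordinate
#' array. The topology carries, per atom: `chain`, `resid` (1-based,
#' contiguous within a chain), `resname`, `name`, `element`, `mass`
#' (amu), partial `charge` (e) and `radius` (A).
#'
#' @param topology data frame as described above.
#' @param coords numeric array `n_atoms x 3 x n_frames` (a single
#'   `n_atoms x 3` matrix is promoted to one frame).
#' @return An object of class `"trajectory"`.
#' @export
trajectory <- function(topology, coords) {
  topology <- as.data.frame(topology)
  need <- c("chain", "resid", "resname", "name", "element", "mass",
            "charge", "radius")
  miss <- setdiff(need, names(topology))
  if (length(miss)) {
    stop("topology is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  if (any(topology$mass <= 0)) stop("masses must be > 0", call. = FALSE)
  if (any(topology$radius < 0)) stop("radii must be >= 0", call. = FALSE)
  if (is.matrix(coords)) coords <- array(coords, dim = c(dim(coords), 1L))
  stopifnot(length(dim(coords)) == 3L, dim(coords)[2] == 3L,
            dim(coords)[1] == nrow(topology))
  structure(list(topology = topology, coords = coords),
            class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("Trajectory: %d atoms, %d frame(s), chains %s\n",
              nrow(x$topology), n_frames(x),
              paste(unique(x$topology$chain), collapse = ", ")))
  invisible(x)
}

#' Number of frames in a trajectory
#' @param traj a `"trajectory"`.
#' @return Integer frame count.
#' @export
n_frames <- function(traj) {
  stopifnot(inherits(traj, "trajectory"))
  dim(traj$coords)[3]
}

#' Extract one frame as a coordinate matrix
#'
#' @param traj a `"trajectory"` or an `n_atoms x 3` matrix (returned
#'   unchanged).
#' @param frame frame index.
#' @return `n_atoms x 3` numeric matrix.
#' @export
as_frame <- function(traj, frame = 1L) {
  if (is.matrix(traj)) return(traj)
  stopifnot(inherits(traj, "trajectory"))
  m <- traj$coords[, , frame]
  if (!is.matrix(m)) m <- matrix(m, ncol = 3L)
  m
}

#' Select atoms with a small selection language
#'
#' The selection string is a space-separated sequence of clauses, all of
#' which must hold (logical AND):
#' \describe{
#'   \item{`all`}{every atom (the default).}
#'   \item{`chain X`}{atoms in chain `X` (several: `chain A B`).}
#'   \item{`resid a-b` / `resid a b c`}{closed residue ranges or lists.}
#'   \item{`backbone`}{atom names N, CA, C, O.}
#'   \item{`heavy`}{element not hydrogen.}
#'   \item{`name X [Y ...]`}{atom names.}
#' }
#'
#' @param topology an atom table (or a `"trajectory"`).
#' @param selection selection string, e.g. `"chain A resid 1-44 backbone"`.
#' @return Integer vector of atom indices; errors if empty.
#' @export
select_atoms <- function(topology, selection = "all") {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  keep <- rep(TRUE, nrow(topology))
  tok <- strsplit(trimws(selection), "\\s+")[[1]]
  i <- 1L
  grab <- function(i) {
    # consume argument tokens until the next keyword
    kw <- c("chain", "resid", "backbone", "heavy", "all", "name")
    j <- i
    while (j <= length(tok) && !(tok[j] %in% kw)) j <- j + 1L
    j
  }
  while (i <= length(tok)) {
    word <- tok[i]
    if (word == "all") {
      i <- i + 1L
    } else if (word == "backbone") {
      keep <- keep & topology$name %in% c("N", "CA", "C", "O")
      i <- i + 1L
    } else if (word == "heavy") {
      keep <- keep & !(toupper(topology$element) %in% c("H", "D"))
      i <- i + 1L
    } else if (word == "chain") {
      j <- grab(i + 1L)
      if (j == i + 1L) stop("`chain` needs an argument", call. = FALSE)
      keep <- keep & topology$chain %in% tok[(i + 1L):(j - 1L)]
      i <- j
    } else if (word == "name") {
      j <- grab(i + 1L)
      if (j == i + 1L) stop("`name` needs an argument", call. = FALSE)
      keep <- keep & topology$name %in% tok[(i + 1L):(j - 1L)]
      i <- j
    } else if (word == "resid") {
      j <- grab(i + 1L)
      if (j == i + 1L) stop("`resid` needs an argument", call. = FALSE)
      ids <- integer()
      for (arg in tok[(i + 1L):(j - 1L)]) {
        if (grepl("^\\d+-\\d+$", arg)) {
          ab <- as.integer(strsplit(arg, "-")[[1]])
          ids <- c(ids, seq(ab[1], ab[2]))
        } else {
          ids <- c(ids, as.integer(arg))
        }
      }
      keep <- keep & topology$resid %in% ids
      i <- j
    } else {
      stop(sprintf("unknown selection token `%s`", word), call. = FALSE)
    }
  }
  out <- which(keep)
  if (!length(out)) {
    stop(sprintf("selection `%s` matches no atoms", selection),
         call. = FALSE)
  }
  out
}

# Resolve a selection argument: indices, logical mask, or language string.
resolve_selection <- function(topology, sel) {
  if (inherits(topology, "trajectory")) topology <- topology$topology
  if (is.character(sel)) return(select_atoms(topology, sel))
  if (is.logical(sel)) return(which(sel))
  sel <- as.integer(sel)
  if (!length(sel)) stop("empty selection", call. = FALSE)
  if (any(sel < 1L | sel > nrow(topology))) {
    stop("selection index out of range", call. = FALSE)
  }
  sel
}
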