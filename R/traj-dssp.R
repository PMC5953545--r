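# Secondary structure by backbone hydrogen-bond patterns (Kabsch-Sander).
#
# The electrostatic H-bond energy between an acceptor carbonyl (C=O of
# residue a) and a donor amide (N-H of residue d) is
#   E = 0.084 * 332 * (1/r_ON + 1/r_CH - 1/r_OH - 1/r_CN)  kcal/mol,
# with a bond called at E < -0.5. Amide hydrogens are built
# geometrically (H = N + unit(C_prev - O_prev)) when absent from the
# topology. Simplifications relative to full DSSP, each deliberate:
# chain breaks end ladders and turns; assignment priority is
# 4-helix > bridge/ladder > 3-helix > 5-helix > turn; bends (S) are not
# assigned (they map to coil in the four-category scheme regardless).

DSSP_Q <- 0.084 * 332  # kcal/mol * Angstrom
DSSP_EMAX <- -0.5      # kcal/mol bond threshold
DSSP_CA_CUTOFF <- 9.0  # Angstrom prefilter on CA-CA distance

# Residue bookkeeping for one frame: backbone atom rows per residue.
dssp_residue_table <- function(top) {
  key <- paste(top$chain, top$resid)
  resk <- unique(key)
  find <- function(k, atom) {
    j <- which(key == k & top$name == atom)
    if (length(j) == 1L) j else NA_integer_
  }
  data.frame(
    chain = top$chain[match(resk, key)],
    resid = top$resid[match(resk, key)],
    iN = vapply(resk, find, 0L, "N"),
    iCA = vapply(resk, find, 0L, "CA"),
    iC = vapply(resk, find, 0L, "C"),
    iO = vapply(resk, find, 0L, "O"),
    iH = vapply(resk, find, 0L, "H"),
    row.names = NULL, stringsAsFactors = FALSE)
}

#' Classify secondary structure of one frame
#'
#' Assigns each residue one of four categories — `helix` (DSSP G/H/I),
#' `sheet` (E/B), `turn` (T) or `coil` — from backbone hydrogen-bond
#' patterns computed with the Kabsch-Sander energy. Residues with
#' missing backbone atoms are reported as coil and flagged.
#'
#' @param traj a `"trajectory"` with backbone N/CA/C/O atoms (amide H
#'   optional; built geometrically when absent).
#' @param frame frame index.
#' @param chain restrict output to one chain (H-bonds are still searched
#'   across all chains).
#' @return Character vector of categories named `chain:resid`, with
#'   attributes `"dssp"` (the underlying letter per residue; `"C"` for
#'   coil) and `"incomplete"` (logical flag per residue).
#' @export
dssp_classify <- function(traj, frame = 1L, chain = NULL) {
  stopifnot(inherits(traj, "trajectory"))
  top <- traj$topology
  xyz <- as_frame(traj, frame)
  rt <- dssp_residue_table(top)
  n <- nrow(rt)
  if (n < 3L) stop("need at least 3 residues", call. = FALSE)
  complete <- !is.na(rt$iN) & !is.na(rt$iCA) & !is.na(rt$iC) &
    !is.na(rt$iO)
  if (any(!complete)) {
    warning(sprintf("%d residue(s) with missing backbone atoms -> coil",
                    sum(!complete)), call. = FALSE)
  }
  # same-chain predecessor with no residue-number gap
  prev <- rep(NA_integer_, n)
  for (i in 2:n) {
    if (rt$chain[i] == rt$chain[i - 1L] &&
        rt$resid[i] == rt$resid[i - 1L] + 1L) {
      prev[i] <- i - 1L
    }
  }
  # donor H per residue: explicit, else built from the previous carbonyl
  hpos <- matrix(NA_real_, n, 3L)
  for (i in seq_len(n)) {
    if (!complete[i]) next
    if (!is.na(rt$iH[i])) {
      hpos[i, ] <- xyz[rt$iH[i], ]
    } else if (!is.na(prev[i]) && complete[prev[i]]) {
      co <- xyz[rt$iC[prev[i]], ] - xyz[rt$iO[prev[i]], ]
      hpos[i, ] <- xyz[rt$iN[i], ] + co / sqrt(sum(co^2))
    }
  }
  # hb[a, d]: CO of a accepts from NH of d
  hb <- matrix(FALSE, n, n)
  ca <- xyz[rt$iCA, , drop = FALSE]
  for (a in seq_len(n)) {
    if (!complete[a]) next
    for (d in seq_len(n)) {
      if (d == a || !complete[d] || anyNA(hpos[d, ])) next
      if (!is.na(prev[d]) && prev[d] == a) next  # directly bonded pair
      if (sum((ca[a, ] - ca[d, ])^2) > DSSP_CA_CUTOFF^2) next
      rON <- sqrt(sum((xyz[rt$iO[a], ] - xyz[rt$iN[d], ])^2))
      rCH <- sqrt(sum((xyz[rt$iC[a], ] - hpos[d, ])^2))
      rOH <- sqrt(sum((xyz[rt$iO[a], ] - hpos[d, ])^2))
      rCN <- sqrt(sum((xyz[rt$iC[a], ] - xyz[rt$iN[d], ])^2))
      if (min(rON, rCH, rOH, rCN) < 0.5) next  # atom clash guard
      e <- DSSP_Q * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      hb[a, d] <- e < DSSP_EMAX
    }
  }
  # contiguous same-chain run membership for i..i+k spans
  contig <- function(i, k) {
    j <- i + k
    j <= n && rt$chain[i] == rt$chain[j] &&
      rt$resid[j] == rt$resid[i] + k
  }
  turn_n <- sapply(3:5, function(nn) {
    vapply(seq_len(n), function(i)
      contig(i, nn) && hb[i, i + nn], logical(1))
  })  # n x 3 (columns: 3,4,5-turns)
  letters_out <- rep("C", n)
  # helices: n-helix from i when consecutive n-turns at i-1 and i
  mark_helix <- function(nn, letter, occupied) {
    col <- nn - 2L
    hit <- rep(FALSE, n)
    for (i in 2:n) {
      if (turn_n[i - 1L, col] && turn_n[i, col]) {
        hit[i:min(n, i + nn - 1L)] <- TRUE
      }
    }
    hit & !occupied
  }
  isH <- mark_helix(4L, "H", rep(FALSE, n))
  # bridges
  bridge <- matrix(FALSE, n, n)
  for (i in 2:(n - 1L)) {
    if (!contig(i - 1L, 2L)) next
    for (j in 2:(n - 1L)) {
      if (abs(i - j) < 3L && rt$chain[i] == rt$chain[j]) next
      if (!contig(j - 1L, 2L)) next
      par <- (hb[i - 1L, j] && hb[j, i + 1L]) ||
        (hb[j - 1L, i] && hb[i, j + 1L])
      anti <- (hb[i, j] && hb[j, i]) ||
        (hb[i - 1L, j + 1L] && hb[j - 1L, i + 1L])
      if (par || anti) bridge[i, j] <- TRUE
    }
  }
  isBridge <- apply(bridge, 1L, any)
  # ladder: bridge with an adjacent bridge partner -> E, isolated -> B
  isE <- rep(FALSE, n)
  for (i in which(isBridge)) {
    js <- which(bridge[i, ])
    ext <- any(vapply(js, function(j) {
      (i > 1L && any(bridge[i - 1L, max(1L, j - 1L):min(n, j + 1L)])) ||
        (i < n && any(bridge[i + 1L, max(1L, j - 1L):min(n, j + 1L)]))
    }, logical(1)))
    isE[i] <- ext
  }
  sheet <- isBridge & !isH
  isG <- mark_helix(3L, "G", isH | sheet)
  isI <- mark_helix(5L, "I", isH | sheet | isG)
  # turns: interior residues of any n-turn
  isT <- rep(FALSE, n)
  for (col in 1:3) {
    nn <- col + 2L
    for (i in which(turn_n[, col])) {
      isT[(i + 1L):(i + nn - 1L)] <- TRUE
    }
  }
  letters_out[isT] <- "T"
  letters_out[isI] <- "I"
  letters_out[isG] <- "G"
  letters_out[sheet & isE] <- "E"
  letters_out[sheet & !isE] <- "B"
  letters_out[isH] <- "H"
  letters_out[!complete] <- "C"
  category <- c(H = "helix", G = "helix", I = "helix", E = "sheet",
                B = "sheet", T = "turn", C = "coil")[letters_out]
  names(category) <- paste0(rt$chain, ":", rt$resid)
  keep <- if (is.null(chain)) seq_len(n) else which(rt$chain == chain)
  out <- category[keep]
  attr(out, "dssp") <- letters_out[keep]
  attr(out, "incomplete") <- !complete[keep]
  out
}

#' Secondary-structure record over an ensemble
#'
#' Runs [dssp_classify()] on every frame.
#'
#' @param traj a `"trajectory"`.
#' @param chain restrict to one chain.
#' @return Character matrix `n_frames x n_residues` of categories, class
#'   `"ss_record"`.
#' @export
dssp_trajectory <- function(traj, chain = NULL) {
  rows <- lapply(seq_len(n_frames(traj)), function(fr)
    dssp_classify(traj, fr, chain))
  m <- do.call(rbind, lapply(rows, as.vector))
  colnames(m) <- names(rows[[1]])
  class(m) <- c("ss_record", class(m))
  m
}

#' Summarise secondary-structure content
#'
#' Per residue, the percentage of frames spent in each category; the
#' overall value per category is the mean of those per-residue
#' percentages over the selected residues (so every residue carries
#' equal weight regardless of frame count).
#'
#' @param record an `"ss_record"` (frames x residues), or any character
#'   matrix of categories.
#' @param residues optional column names or indices to average over.
#' @return List with `per_residue` (data frame of percentages, rows =
#'   residues) and `overall` (named vector summing to 100).
#' @export
ss_summary <- function(record, residues = NULL) {
  m <- unclass(record)
  if (!is.matrix(m) || nrow(m) < 1L) {
    stop("empty secondary-structure record", call. = FALSE)
  }
  if (!is.null(residues)) m <- m[, residues, drop = FALSE]
  cats <- c("helix", "sheet", "turn", "coil")
  per <- sapply(cats, function(cc) 100 * colMeans(m == cc))
  per <- as.data.frame(per)
  per$residue <- colnames(m) %||% as.character(seq_len(ncol(m)))
  overall <- colMeans(as.matrix(per[, cats, drop = FALSE]))
  list(per_residue = per[, c("residue", cats)], overall = overall)
}
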