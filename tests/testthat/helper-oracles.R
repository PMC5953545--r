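# Independent oracle implementations used only by the tests; they never
# share code with the package internals.

# Horn's quaternion method for the optimal-superposition RMSD of two
# conformations (all atoms, proper rotation implied by the unit
# quaternion).
quaternion_rmsd <- function(a, b) {
  n <- nrow(a)
  a0 <- sweep(a, 2, colMeans(a))
  b0 <- sweep(b, 2, colMeans(b))
  S <- crossprod(a0, b0)
  K <- matrix(c(
    S[1, 1] + S[2, 2] + S[3, 3], S[2, 3] - S[3, 2],
    S[3, 1] - S[1, 3], S[1, 2] - S[2, 1],
    S[2, 3] - S[3, 2], S[1, 1] - S[2, 2] - S[3, 3],
    S[1, 2] + S[2, 1], S[3, 1] + S[1, 3],
    S[3, 1] - S[1, 3], S[1, 2] + S[2, 1],
    -S[1, 1] + S[2, 2] - S[3, 3], S[2, 3] + S[3, 2],
    S[1, 2] - S[2, 1], S[3, 1] + S[1, 3],
    S[2, 3] + S[3, 2], -S[1, 1] - S[2, 2] + S[3, 3]), 4, 4,
    byrow = TRUE)
  lam <- max(eigen(K, symmetric = TRUE, only.values = TRUE)$values)
  msd <- (sum(a0^2) + sum(b0^2) - 2 * lam) / n
  sqrt(max(0, msd))
}

# A second, from-scratch Kabsch-Sander assignment collapsed to the four
# categories. Residues are handled as a flat list of per-residue
# records; hydrogen bonds are collected as an explicit edge list.
oracle_dssp <- function(traj, frame = 1) {
  top <- traj$topology
  xyz <- as_frame(traj, frame)
  key <- paste(top$chain, top$resid)
  uk <- unique(key)
  res <- lapply(uk, function(k) {
    rows <- which(key == k)
    at <- function(nm) {
      r <- rows[top$name[rows] == nm]
      if (length(r) == 1) xyz[r, ] else NULL
    }
    list(chain = top$chain[rows[1]], resid = top$resid[rows[1]],
         N = at("N"), CA = at("CA"), C = at("C"), O = at("O"),
         H = at("H"))
  })
  nres <- length(res)
  full <- vapply(res, function(r)
    !is.null(r$N) && !is.null(r$CA) && !is.null(r$C) && !is.null(r$O),
    logical(1))
  linked <- function(i, j) {
    # j follows i directly in the same chain
    res[[i]]$chain == res[[j]]$chain &&
      res[[j]]$resid == res[[i]]$resid + (j - i) && j - i >= 0
  }
  pred <- vapply(seq_len(nres), function(i) {
    if (i > 1 && res[[i - 1]]$chain == res[[i]]$chain &&
        res[[i - 1]]$resid == res[[i]]$resid - 1) i - 1L else NA_integer_
  }, integer(1))
  hcoord <- function(i) {
    if (!is.null(res[[i]]$H)) return(res[[i]]$H)
    p <- pred[i]
    if (is.na(p) || !full[p]) return(NULL)
    d <- res[[p]]$C - res[[p]]$O
    res[[i]]$N + d / sqrt(sum(d^2))
  }
  # explicit hydrogen-bond edge list: (acceptor CO, donor NH)
  edges <- matrix(integer(0), 0, 2)
  for (a in seq_len(nres)) {
    if (!full[a]) next
    for (d in seq_len(nres)) {
      if (a == d || !full[d]) next
      if (!is.na(pred[d]) && pred[d] == a) next
      h <- hcoord(d)
      if (is.null(h)) next
      dist <- function(u, v) sqrt(sum((u - v)^2))
      rON <- dist(res[[a]]$O, res[[d]]$N)
      rCH <- dist(res[[a]]$C, h)
      rOH <- dist(res[[a]]$O, h)
      rCN <- dist(res[[a]]$C, res[[d]]$N)
      if (min(rON, rCH, rOH, rCN) < 0.5) next
      e <- 0.084 * 332 * (1 / rON + 1 / rCH - 1 / rOH - 1 / rCN)
      if (e < -0.5) edges <- rbind(edges, c(a, d))
    }
  }
  hbond <- function(a, d) {
    any(edges[, 1] == a & edges[, 2] == d)
  }
  span_ok <- function(i, k) {
    j <- i + k
    j <= nres && res[[i]]$chain == res[[j]]$chain &&
      res[[j]]$resid == res[[i]]$resid + k
  }
  turn <- function(i, k) span_ok(i, k) && hbond(i, i + k)
  cat4 <- rep("coil", nres)
  in_helix <- function(k) {
    hit <- rep(FALSE, nres)
    for (i in 2:nres) {
      if (turn(i - 1, k) && turn(i, k)) {
        hit[i:min(nres, i + k - 1)] <- TRUE
      }
    }
    hit
  }
  hH <- in_helix(4)
  # bridges
  brid <- rep(FALSE, nres)
  bpairs <- list()
  for (i in 2:(nres - 1)) {
    if (!span_ok(i - 1, 2)) next
    for (j in 2:(nres - 1)) {
      if (!span_ok(j - 1, 2)) next
      if (res[[i]]$chain == res[[j]]$chain && abs(i - j) < 3) next
      p <- (hbond(i - 1, j) && hbond(j, i + 1)) ||
        (hbond(j - 1, i) && hbond(i, j + 1))
      ap <- (hbond(i, j) && hbond(j, i)) ||
        (hbond(i - 1, j + 1) && hbond(j - 1, i + 1))
      if (p || ap) {
        brid[i] <- TRUE
        bpairs[[length(bpairs) + 1]] <- c(i, j)
      }
    }
  }
  sheet <- brid & !hH
  hG <- in_helix(3) & !hH & !sheet
  hI <- in_helix(5) & !hH & !sheet & !hG
  tt <- rep(FALSE, nres)
  for (k in 3:5) {
    for (i in seq_len(nres)) {
      if (turn(i, k)) tt[(i + 1):(i + k - 1)] <- TRUE
    }
  }
  cat4[tt] <- "turn"
  cat4[hI | hG] <- "helix"
  cat4[sheet] <- "sheet"
  cat4[hH] <- "helix"
  cat4[!full] <- "coil"
  names(cat4) <- paste0(vapply(res, `[[`, "", "chain"), ":",
                        vapply(res, function(r) r$resid, 1))
  cat4
}
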