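# Shared fixtures, built in code.

# Tail-peptide titration schedule: 50 uM protein, molar ratios up to 1:10.
fig_schedule <- function(dilution = 1) {
  titration_schedule(50, c(0, 0.1, 0.25, 0.5, 1, 2, 5, 10), dilution)
}

# A titration spec with `n_resp` responding residues (finite saturation
# shifts) among `n_res` total; the remainder do not move. The shift
# layout is deterministic; only the noise draw depends on `seed`.
make_titration_spec <- function(kd, noise = c(0, 0), seed = 1L,
                                n_res = 44L, n_resp = 14L,
                                points = fig_schedule(),
                                responder_delta = NULL) {
  i <- seq_len(n_res)
  apo <- cbind(7.5 + 0.04 * i, 105 + 0.5 * i)
  delta <- matrix(0, n_res, 2L)
  k <- seq_len(n_resp)
  if (is.null(responder_delta)) {
    delta[k, 1] <- (0.06 + 0.015 * k) * (-1)^k
    delta[k, 2] <- (0.4 + 0.08 * k) * (-1)^(k %/% 2)
  } else {
    delta[k, 1] <- responder_delta[1] * (-1)^k
    delta[k, 2] <- responder_delta[2] * (-1)^(k %/% 2)
  }
  titration_spec(residues = sprintf("R%02d", i), apo_shift = apo,
                 bound_shift = apo + delta, kd_true = kd,
                 points = points, noise_sd = noise, seed = seed)
}

# Ideal helical and extended single strands.
make_helix <- function(n = 15) build_backbone(rep(-57, n), rep(-47, n))
make_strand <- function(n = 8, chain = "A") {
  build_backbone(rep(-139, n), rep(135, n), chain = chain)
}

# Two-strand antiparallel sheet: strand B is a rigid copy of strand A
# placed by minimising deviations of the registered inter-strand N...O
# distances from 2.9 A (deterministic optimisation from a fixed start).
make_sheet <- function(n = 8) {
  s1 <- make_strand(n)
  xyz1 <- as_frame(s1)
  top <- s1$topology
  rotv <- function(v) {
    th <- sqrt(sum(v^2))
    if (th < 1e-12) return(diag(3))
    u <- v / th
    K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
    diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  }
  place <- function(p) sweep(xyz1 %*% t(rotv(p[1:3])), 2, -p[4:6])
  iN <- which(top$name == "N")
  iO <- which(top$name == "O")
  pairs <- cbind(seq(2, n - 1, 2), n + 1 - seq(2, n - 1, 2))
  obj <- function(p) {
    xyz2 <- place(p)
    s <- 0
    for (kk in seq_len(nrow(pairs))) {
      i <- pairs[kk, 1]
      j <- pairs[kk, 2]
      s <- s + (sqrt(sum((xyz1[iO[i], ] - xyz2[iN[j], ])^2)) - 2.9)^2
      s <- s + (sqrt(sum((xyz1[iN[i], ] - xyz2[iO[j], ])^2)) - 2.9)^2
    }
    d2 <- outer(rowSums(xyz1^2), rowSums(xyz2^2), "+") -
      2 * tcrossprod(xyz1, xyz2)
    s + 10 * sum(pmax(0, 2.7 - sqrt(pmax(d2, 0)))^2)
  }
  p0 <- c(0, 0, pi, 0, 4.8, 0)
  opt <- optim(p0, obj, method = "Nelder-Mead",
               control = list(maxit = 5000, reltol = 1e-12))
  opt <- optim(opt$par, obj, method = "BFGS",
               control = list(maxit = 500))
  top2 <- top
  top2$chain <- "B"
  trajectory(rbind(top, top2), rbind(xyz1, place(opt$par)))
}

# Random rigid motion applied to an n x 3 coordinate matrix.
random_rigid <- function(xyz) {
  v <- rnorm(3)
  v <- v / sqrt(sum(v^2)) * runif(1, 0, pi)
  th <- sqrt(sum(v^2))
  u <- v / th
  K <- matrix(c(0, u[3], -u[2], -u[3], 0, u[1], u[2], -u[1], 0), 3, 3)
  R <- diag(3) + sin(th) * K + (1 - cos(th)) * (K %*% K)
  sweep(xyz %*% t(R), 2, -rnorm(3, 0, 10))
}
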