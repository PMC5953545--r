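test_that("radius of gyration matches closed-form cases", {
  expect_equal(radius_of_gyration(matrix(c(1, 2, 3), 1, 3)), 0)
  expect_equal(radius_of_gyration(rbind(c(0, 0, 0), c(2, 0, 0))), 1.0)
  sq <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0), c(0, 1, 0))
  expect_equal(radius_of_gyration(sq), sqrt(0.5), tolerance = 1e-12)
  # mass weighting shifts the centre toward the heavy atom
  top <- data.frame(chain = "A", resid = 1:2, resname = "X",
                    name = c("C1", "C2"), element = "C",
                    mass = c(3, 1), charge = 0, radius = 1)
  tr <- trajectory(top, rbind(c(0, 0, 0), c(4, 0, 0)))
  expect_equal(radius_of_gyration(tr), sqrt((3 * 1 + 1 * 9) / 4))
  expect_equal(radius_of_gyration(tr, mass_weighted = FALSE), 2)
})

test_that("Rg and fitted RMSD are invariant to rigid motion", {
  set.seed(21)
  for (rep in 1:10) {
    xyz <- matrix(rnorm(3 * 20, sd = 5), 20, 3)
    moved <- random_rigid(xyz)
    expect_equal(radius_of_gyration(moved), radius_of_gyration(xyz),
                 tolerance = 1e-9)
    expect_lt(kabsch_rmsd(moved, xyz), 1e-9)
  }
})

test_that("kabsch_rmsd agrees with the quaternion oracle", {
  expect_equal(kabsch_rmsd(diag(3), diag(3)), 0)
  set.seed(22)
  for (rep in 1:25) {
    n <- sample(5:50, 1)
    a <- matrix(rnorm(3 * n, sd = 4), n, 3)
    b <- matrix(rnorm(3 * n, sd = 4), n, 3)
    expect_equal(kabsch_rmsd(a, b), quaternion_rmsd(a, b),
                 tolerance = 1e-6)
  }
})

test_that("fitting never increases the RMSD", {
  set.seed(23)
  for (rep in 1:10) {
    n <- sample(5:30, 1)
    a <- matrix(rnorm(3 * n, sd = 4), n, 3)
    b <- matrix(rnorm(3 * n, sd = 4), n, 3)
    raw <- sqrt(mean(rowSums((a - b)^2)))
    expect_lte(kabsch_rmsd(a, b), raw + 1e-12)
  }
})

test_that("core-fit / tail-measure selections separate correctly", {
  set.seed(24)
  core <- matrix(rnorm(30, sd = 3), 10, 3)
  tail0 <- matrix(rnorm(15, sd = 3), 5, 3)
  tail1 <- tail0 + matrix(c(2, 0, 0), 5, 3, byrow = TRUE)
  a <- rbind(core, tail0)
  b <- random_rigid(rbind(core, tail1))
  r <- kabsch_rmsd(b, a, fit_sel = 1:10, rmsd_sel = 11:15)
  expect_equal(r, 2, tolerance = 1e-6)
  expect_error(kabsch_rmsd(matrix(0, 2, 3), matrix(0, 3, 3)),
               "matching")
})

test_that("end-state RMSD averages the strict upper triangle", {
  set.seed(25)
  a <- matrix(rnorm(30), 10, 3)
  expect_equal(end_state_rmsd(list(a, a, a))$mean, 0)
  b <- matrix(rnorm(30), 10, 3)
  two <- end_state_rmsd(list(a, b))
  expect_equal(two$mean, kabsch_rmsd(a, b))
  # two tight clusters far apart: within-group means are much smaller
  jig <- function(m) m + matrix(rnorm(30, sd = 0.05), 10, 3)
  frames <- list(jig(a), jig(a), jig(b), jig(b))
  r <- end_state_rmsd(frames, groups = c(1, 1, 2, 2))
  expect_lt(max(r$group_means), r$mean / 3)
})

test_that("ideal helices are classified helix in agreement with the oracle", {
  hel <- make_helix(15)
  cls <- dssp_classify(hel)
  expect_true(all(cls[4:12] == "helix"))
  orc <- oracle_dssp(hel)
  expect_gte(mean(cls == orc), 0.99)
})

test_that("antiparallel strands form sheet in agreement with the oracle", {
  sheet <- make_sheet(8)
  cls <- dssp_classify(sheet)
  orc <- oracle_dssp(sheet)
  expect_gte(mean(cls == orc), 0.99)
  expect_true(all(cls[c("A:4", "A:5", "B:4", "B:5")] == "sheet"))
})

test_that("short isolated peptides have no secondary structure", {
  tri <- build_backbone(rep(-70, 3), rep(150, 3))
  expect_true(all(dssp_classify(tri) == "coil"))
  di <- build_backbone(rep(-70, 2), rep(150, 2))
  expect_error(dssp_classify(di), "3 residues")
})

test_that("classification agrees with the oracle on perturbed backbones", {
  set.seed(26)
  agree <- total <- 0
  for (rep in 1:6) {
    phi <- rep(-57, 12) + rnorm(12, 0, 6)
    psi <- rep(-47, 12) + rnorm(12, 0, 6)
    tr <- build_backbone(phi, psi)
    cls <- dssp_classify(tr)
    orc <- oracle_dssp(tr)
    agree <- agree + sum(cls == orc)
    total <- total + length(cls)
  }
  expect_gte(agree / total, 0.99)
})

test_that("residues with missing backbone atoms fall back to coil", {
  hel <- make_helix(8)
  keep <- !(hel$topology$resid == 4 & hel$topology$name == "O")
  broken <- trajectory(hel$topology[keep, ],
                       hel$coords[keep, , , drop = FALSE])
  expect_warning(cls <- dssp_classify(broken), "missing backbone")
  expect_equal(as.vector(cls[4]), "coil")
  expect_true(attr(cls, "incomplete")[4])
})

test_that("secondary-structure summaries tally frames per residue", {
  rec <- rbind(rep("coil", 4), rep("coil", 4))
  class(rec) <- c("ss_record", class(rec))
  s <- ss_summary(rec)
  expect_equal(unname(s$overall), c(0, 0, 0, 100))
  # half the frames helix for every residue
  rec2 <- rbind(rep("helix", 4), rep("coil", 4))
  expect_equal(ss_summary(rec2)$overall[["helix"]], 50)
  # mixed record matches a brute-force tally
  set.seed(27)
  cats <- c("helix", "sheet", "turn", "coil")
  rec3 <- matrix(sample(cats, 60, replace = TRUE), 10, 6)
  s3 <- ss_summary(rec3)
  for (j in 1:6) {
    for (cc in cats) {
      expect_equal(s3$per_residue[j, cc],
                   100 * sum(rec3[, j] == cc) / 10)
    }
  }
  expect_error(ss_summary(matrix(character(0), 0, 0)), "empty")
})

test_that("occupancy grids honour exact static and alternating cases", {
  top <- data.frame(chain = "A", resid = 1, resname = "X", name = "C",
                    element = "C", mass = 12, charge = 0, radius = 1)
  static <- trajectory(top, array(rep(c(0.2, 0.3, 0.4), 100),
                                  dim = c(1, 3, 100)))
  g <- occupancy_grid(static, sel = 1)
  expect_equal(sum(g$occupancy > 0), 1L)
  expect_equal(max(g$occupancy), 1.0)
  # atom alternating between two voxels on even/odd frames
  pos <- vapply(1:100, function(fr)
    c(ifelse(fr %% 2, 0.5, 3.5), 0.5, 0.5), numeric(3))
  alt <- trajectory(top, array(pos, dim = c(1, 3, 100)))
  g2 <- occupancy_grid(alt, sel = 1)
  occ <- sort(g2$occupancy[g2$occupancy > 0])
  expect_equal(occ, c(0.5, 0.5))
})

test_that("occupancy is bounded and frame-order invariant", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 20, collapse = 0.5,
                                           n_sweeps = 40, seed = 31))
  g <- occupancy_grid(tr, sel = "chain A")
  expect_true(all(g$occupancy >= 0 & g$occupancy <= 1))
  perm <- sample(20)
  tr2 <- tr
  tr2$coords <- tr$coords[, , perm]
  g2 <- occupancy_grid(tr2, sel = "chain A")
  expect_equal(sort(grid_voxels(g)$occupancy),
               sort(grid_voxels(g2)$occupancy))
  expect_equal(g$occupancy, g2$occupancy)
})

test_that("collapsed ensembles concentrate occupancy at the DNA surface", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 100, collapse = 1,
                                           seed = 11))
  g <- occupancy_grid(tr, sel = "chain A")
  v <- grid_voxels(g)
  rad <- sqrt(v$x^2 + v$y^2)
  zex <- pmax(0, abs(v$z) - 20)
  d_surface <- sqrt(pmax(0, rad - 10)^2 + zex^2)
  frac <- sum(v$occupancy[d_surface <= 5]) / sum(v$occupancy)
  expect_gte(frac, 0.9)
})

test_that("count-mode occupancy records mean atoms per voxel", {
  top <- data.frame(chain = "A", resid = 1:2, resname = "X",
                    name = c("C1", "C2"), element = "C", mass = 12,
                    charge = 0, radius = 1)
  xyz <- aperm(array(rep(t(rbind(c(0.4, 0.5, 0.5), c(0.6, 0.5, 0.5))),
                         10), dim = c(3, 2, 10)), c(2, 1, 3))
  tr <- trajectory(top, xyz)
  g <- occupancy_grid(tr, sel = 1:2, mode = "count")
  expect_equal(max(g$occupancy), 2)  # both atoms share one voxel
  gf <- occupancy_grid(tr, sel = 1:2, mode = "fraction")
  expect_equal(max(gf$occupancy), 1)
})

test_that("OpenDX output round-trips shape and values", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 5, collapse = 0.5,
                                           n_sweeps = 30, seed = 33))
  g <- occupancy_grid(tr, sel = "chain A")
  path <- withr::local_tempfile(fileext = ".dx")
  write_opendx(g, path)
  lines <- readLines(path)
  expect_match(lines[1], sprintf("counts %d %d %d", g$shape[1],
                                 g$shape[2], g$shape[3]))
  hdr <- grep("data follows", lines)
  vals <- as.numeric(unlist(strsplit(trimws(
    lines[(hdr + 1):(length(lines) - 1)]), "\\s+")))
  expect_equal(length(vals), prod(g$shape))
  expect_equal(sum(vals), sum(g$occupancy), tolerance = 1e-4)
})

test_that("SASA matches closed forms and is additive when disjoint", {
  top1 <- data.frame(chain = "A", resid = 1, resname = "X", name = "C",
                     element = "C", mass = 12, charge = 0, radius = 1.9)
  single <- sasa(trajectory(top1, matrix(0, 1, 3)))$total
  expect_equal(single, 4 * pi * 3.3^2, tolerance = 1e-9)
  # complete occlusion by a tight cage of large atoms
  cage <- rbind(c(3, 0, 0), c(-3, 0, 0), c(0, 3, 0), c(0, -3, 0),
                c(0, 0, 3), c(0, 0, -3))
  topc <- data.frame(chain = "A", resid = 1:7, resname = "X",
                     name = "C", element = "C", mass = 12, charge = 0,
                     radius = c(1.0, rep(4, 6)))
  caged <- sasa(trajectory(topc, rbind(c(0, 0, 0), cage)), sel = 1)
  expect_equal(caged$total, 0)
  # two well-separated atoms double the single-atom value
  top2 <- data.frame(chain = "A", resid = 1:2, resname = "X",
                     name = "C", element = "C", mass = 12, charge = 0,
                     radius = 1.9)
  pair <- sasa(trajectory(top2, rbind(c(0, 0, 0), c(50, 0, 0))))$total
  expect_equal(pair, 2 * single, tolerance = 1e-9)
})

test_that("SASA converges under sphere-point doubling", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 1, collapse = 1,
                                           n_sweeps = 40, seed = 35))
  s1 <- sasa(tr, sel = "chain A", n_points = 960)$total
  s2 <- sasa(tr, sel = "chain A", n_points = 1920)$total
  expect_lt(abs(s2 - s1) / s1, 0.005)
})

test_that("interaction energies follow the screened Coulomb model", {
  top <- data.frame(chain = c("A", "B"), resid = 1, resname = "X",
                    name = "Q", element = "C", mass = 12,
                    charge = c(1, -1), radius = 1)
  xyz <- rbind(c(0, 0, 0), c(3.320636, 0, 0))
  tr <- trajectory(top, xyz)
  expect_equal(interaction_energy(tr, "chain A", "chain B",
                                  dielectric = "constant"), -100,
               tolerance = 1e-9)
  # screened default divides by 4 r^2
  expect_equal(interaction_energy(tr, "chain A", "chain B"),
               -100 / (4 * 3.320636), tolerance = 1e-9)
  # zero charges give zero energy
  top0 <- top
  top0$charge <- 0
  expect_equal(interaction_energy(trajectory(top0, xyz), "chain A",
                                  "chain B"), 0)
  # linearity in charge
  top2 <- top
  top2$charge <- c(2, -1)
  expect_equal(interaction_energy(trajectory(top2, xyz), "chain A",
                                  "chain B", dielectric = "constant"),
               -200, tolerance = 1e-9)
  expect_error(interaction_energy(tr, 1:2, 2), "disjoint")
  xyz0 <- rbind(c(0, 0, 0), c(0, 0, 0))
  expect_error(interaction_energy(trajectory(top, xyz0), 1, 2), "r = 0")
})

test_that("per-residue decomposition reports SEM across tail samples", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 6, n_tails = 2,
                                           collapse = 0.8,
                                           n_sweeps = 40, seed = 41))
  dec <- per_residue_energy(tr)
  expect_equal(dec$n_samples, 2L)
  expect_equal(nrow(dec$per_residue), 10L)
  expect_true(all(dec$per_residue$sem >= 0))
  expect_equal(dec$total, sum(dec$per_residue$mean))
  # single frame, single tail: SEM is absent, not zero
  tr1 <- simulate_tail_trajectory(traj_spec(n_frames = 1, n_tails = 1,
                                            collapse = 0.8,
                                            n_sweeps = 40, seed = 42))
  dec1 <- per_residue_energy(tr1, tail_chains = "A")
  expect_equal(dec1$n_samples, 1L)
  expect_true(all(is.na(dec1$per_residue$sem)))
  expect_true(is.na(dec1$total_sem))
  # identical samples give SEM exactly zero
  dup <- per_residue_energy(list(tr1, tr1), tail_chains = "A")
  expect_equal(dup$n_samples, 2L)
  expect_true(all(dup$per_residue$sem == 0))
})

test_that("neutralizing tail charges weakens the tail-DNA energy", {
  q_full <- c(1, 1.5, 0, 1, 0, 0, 1.5, 1, 1, 1.5)
  q_quad <- q_full
  q_quad[q_full == 1] <- 0          # neutralize the four lysine-like
  q_arg <- q_full
  q_arg[q_full == 1.5] <- 0         # neutralize the three largest
  tot <- function(q, seeds = 1:2) {
    e <- vapply(seeds, function(s) {
      tr <- simulate_tail_trajectory(
        traj_spec(n_frames = 40, n_tails = 2, collapse = 1,
                  tail_charges = q, n_sweeps = 60, seed = 500 + s))
      per_residue_energy(tr)$total
    }, numeric(1))
    mean(e)
  }
  e_full <- tot(q_full)
  e_quad <- tot(q_quad)
  e_arg <- tot(q_arg)
  expect_lt(abs(e_quad), abs(e_full))
  expect_lt(abs(e_arg), abs(e_quad))
})

test_that("selection language resolves chains, ranges, and atom classes", {
  tr <- simulate_tail_trajectory(traj_spec(n_frames = 1, n_tails = 2,
                                           n_sweeps = 5, seed = 2))
  expect_length(select_atoms(tr, "chain A"), 10L)
  expect_length(select_atoms(tr, "chain A resid 1-4"), 4L)
  expect_length(select_atoms(tr, "chain A B resid 2 4 6"), 6L)
  expect_length(select_atoms(tr, "name P"), 60L)
  hel <- make_helix(5)
  expect_length(select_atoms(hel, "backbone"), 20L)
  expect_error(select_atoms(tr, "resid 999"), "no atoms")
  expect_error(select_atoms(tr, "bogus"), "unknown")
})
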