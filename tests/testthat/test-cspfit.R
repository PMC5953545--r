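test_that("composite shift combines the two dimensions correctly", {
  expect_equal(composite_csp(0.1, 0), 0.1)
  expect_equal(composite_csp(0, 1.0), 0.154)
  expect_equal(composite_csp(0.03, 0.2), 0.04300, tolerance = 1e-4)
  # symmetric in sign, and bounded below by each scaled component
  set.seed(8)
  dh <- rnorm(50, 0, 0.1)
  dn <- rnorm(50, 0, 1)
  expect_equal(composite_csp(dh, dn), composite_csp(-dh, -dn))
  expect_true(all(composite_csp(dh, dn) >= abs(dh) - 1e-12))
  expect_true(all(composite_csp(dh, dn) >= 0.154 * abs(dn) - 1e-12))
  expect_error(composite_csp(NA, 1), "dh")
})

test_that("csp_profile references the apo point and flags broadened peaks", {
  spec <- make_titration_spec(12, c(0, 0), n_res = 6, n_resp = 6)
  ser <- simulate_titration(spec)
  # identical series at all points -> all zero
  flat <- ser
  for (p in 2:8) {
    flat$h[, p] <- flat$h[, 1]
    flat$n[, p] <- flat$n[, 1]
  }
  pr0 <- csp_profile(flat)
  expect_true(all(pr0$dd == 0))
  # noiseless generator output equals fraction_bound * ddmax
  pr <- csp_profile(ser)
  f <- fraction_bound(ser$p_conc, ser$l_conc, 12)
  ddmax <- composite_csp(spec$bound_shift[, 1] - spec$apo_shift[, 1],
                         spec$bound_shift[, 2] - spec$apo_shift[, 2])
  for (i in 1:6) {
    expect_equal(pr$dd[i, ], ddmax[i] * f, tolerance = 1e-10,
                 ignore_attr = TRUE)
  }
  # missing at the final point: flagged, not dropped
  ser2 <- simulate_titration(spec, missing = list(R02 = 8))
  expect_warning(pr2 <- csp_profile(ser2), "R02")
  expect_true(pr2$broadened[2])
  expect_equal(length(pr2$residues), 6L)
  # absent at the apo point is an error
  ser3 <- ser
  ser3$h[1, 1] <- NA
  expect_error(csp_profile(ser3), "apo")
})

test_that("significance rule: mean + k*sd with strict inequality", {
  spec <- make_titration_spec(12, c(0, 0), n_res = 10, n_resp = 10)
  ser <- simulate_titration(spec)
  pr <- csp_profile(ser)
  # all equal -> empty set (sd = 0, strict inequality)
  pr_eq <- pr
  pr_eq$dd_eval <- rep(0.1, 10)
  expect_length(select_significant(pr_eq), 0)
  # nine at 0.1, one at 1.0: threshold 0.325 with population sd
  pr_mix <- pr
  pr_mix$dd_eval <- c(1.0, rep(0.1, 9))
  sel <- select_significant(pr_mix)
  expect_equal(as.vector(sel), pr$residues[1])
  expect_equal(attr(sel, "threshold"), 0.325, tolerance = 1e-12)
  # invariant to residue ordering
  perm <- sample(10)
  pr_perm <- pr_mix
  pr_perm$residues <- pr_mix$residues[perm]
  pr_perm$dd_eval <- pr_mix$dd_eval[perm]
  expect_setequal(as.vector(select_significant(pr_perm)),
                  as.vector(sel))
})

test_that("responders are selected exactly on generator ground truth", {
  # 14 responders with a uniform ~0.3 ppm saturation shift, 30 silent
  spec <- make_titration_spec(12, c(0.002, 0.013), seed = 31,
                              responder_delta = c(0.25, 1.1))
  ser <- simulate_titration(spec)
  sel <- select_significant(csp_profile(ser))
  expect_setequal(as.vector(sel), sprintf("R%02d", 1:14))
})

test_that("per-residue fits invert the noiseless generator exactly", {
  for (kd in c(1, 12, 180, 1000)) {
    spec <- make_titration_spec(kd, c(0, 0), n_res = 3, n_resp = 3)
    ser <- simulate_titration(spec)
    pr <- csp_profile(ser)
    for (i in 1:3) {
      f <- fit_residue(pr$dd[i, ], pr$p_conc, pr$l_conc)
      expect_true(f$converged)
      expect_equal(f$kd, kd, tolerance = 1e-3)
      dmax <- composite_csp(spec$bound_shift[i, 1] - spec$apo_shift[i, 1],
                            spec$bound_shift[i, 2] - spec$apo_shift[i, 2])
      expect_equal(f$ddmax, dmax, tolerance = 1e-3)
    }
  }
})

test_that("degenerate residue series are flagged, not fitted", {
  flat <- fit_residue(rep(0, 8), rep(50, 8), c(0, 5, 12, 25, 50, 100,
                                               250, 500))
  expect_false(flat$converged)
  expect_true(is.na(flat$kd))
  expect_error(fit_residue(c(0, 0.1), c(50, 50), c(0, 25)), "3")
})

test_that("Kd aggregation screens outliers in a single pass", {
  expect_equal(aggregate_kd(c(10, 10, 10)),
               list(kd_mean = 10, kd_sd = 0,
                    retained = rep(TRUE, 3),
                    first_pass = list(mean = 10, sd = 0)))
  # 14 x 10 and one 100: population-sd bounds [-28.9, 60.9]
  agg <- aggregate_kd(c(rep(10, 14), 100))
  expect_false(agg$retained[15])
  expect_equal(agg$kd_mean, 10)
  expect_equal(agg$kd_sd, 0)
  expect_equal(agg$first_pass$mean, 16)
  expect_equal(agg$first_pass$sd, 22.44994, tolerance = 1e-6)
  # nothing removed when all values are consistent
  agg2 <- aggregate_kd(c(10, 11, 9, 10, 12))
  expect_true(all(agg2$retained))
  expect_equal(agg2$kd_mean, 10.4)
  expect_error(aggregate_kd(c(10, 11)), "3")
})

test_that("aggregation is idempotent in the single-outlier regime", {
  # consistent per-residue fits plus at most one stray value: the pass-1
  # bounds drop only the stray, and a second pass removes nothing more
  cluster <- 10 + 0.3 * sin(1:12)
  for (stray in c(40, 0.5, NULL)) {
    kds <- c(cluster, stray)
    agg <- aggregate_kd(kds)
    agg2 <- aggregate_kd(kds[agg$retained])
    expect_true(all(agg2$retained))
    expect_equal(agg2$kd_mean, agg$kd_mean)
  }
})

test_that("fold changes are plain Kd ratios", {
  expect_equal(fold_change(180, 12), 15)
  expect_equal(fold_change(7, 7), 1)
  expect_equal(fold_change(7, 14), 0.5)
  expect_error(fold_change(0, 5), "kd_a")
})

test_that("the full pipeline recovers the truth on noiseless data", {
  spec <- make_titration_spec(12, c(0, 0),
                              responder_delta = c(0.25, 1.1))
  fit <- fit_titration(simulate_titration(spec))
  expect_equal(fit$kd_mean, 12, tolerance = 1e-3)
  expect_lt(fit$kd_sd, 0.01)
  # all 14 responders are fitted; on exactly flat Kd sets the +/-2 sd
  # screen may drop one on numerically trivial differences
  expect_equal(nrow(fit$fits), 14L)
  expect_gte(fit$n_retained, 13L)
  expect_s3_class(fit, "csp_titration_fit")
  expect_named(coef(fit), c("kd", "kd_sd"))
  pred <- predict(fit)
  expect_equal(dim(pred), c(14L, 8L))
})

test_that("a corrupted responder is removed by the +/-2 sd screen", {
  spec <- make_titration_spec(12, c(0, 0),
                              responder_delta = c(0.25, 1.1))
  ser <- simulate_titration(spec)
  # replace one responder: still strongly perturbed (so it passes the
  # significance filter) but with a far-off Kd
  bad <- titration_spec("X", spec$apo_shift[1, , drop = FALSE],
                        spec$apo_shift[1, , drop = FALSE] + c(0.3, 1.5),
                        kd_true = 150, points = fig_schedule(),
                        noise_sd = c(0, 0))
  bser <- simulate_titration(bad)
  ser$h[1, ] <- bser$h[1, ]
  ser$n[1, ] <- bser$n[1, ]
  fit <- fit_titration(ser)
  expect_false(fit$fits$retained[fit$fits$residue == "R01"])
  expect_equal(fit$kd_mean, 12, tolerance = 1e-3)
})

test_that("titrations missing half the residues at the end still run", {
  spec <- make_titration_spec(12, c(0, 0),
                              responder_delta = c(0.25, 1.1))
  miss <- setNames(as.list(rep(8, 22)), sprintf("R%02d", seq(1, 44, 2)))
  ser <- simulate_titration(spec, missing = miss)
  expect_warning(fit <- fit_titration(ser), "unobserved")
  # only observable responders contribute
  expect_true(all(fit$fits$residue %in% sprintf("R%02d", seq(2, 14, 2))))
  expect_equal(fit$kd_mean, 12, tolerance = 1e-3)
})

test_that("dilution of the protein across points is handled in the fit", {
  spec <- make_titration_spec(12, c(0, 0), points = fig_schedule(0.97),
                              responder_delta = c(0.25, 1.1))
  expect_true(all(diff(spec$points$p_conc) < 0))
  fit <- fit_titration(simulate_titration(spec))
  expect_equal(fit$kd_mean, 12, tolerance = 1e-3)
})

test_that("noisy replicate fits recover Kd without bias", {
  kds <- vapply(1:20, function(s) {
    ser <- simulate_titration(make_titration_spec(12, c(0.002, 0.013),
                                                  seed = 100 + s))
    fit_titration(ser)$kd_mean
  }, numeric(1))
  expect_lt(abs(median(kds) / 12 - 1), 0.1)
})

test_that("reports are written as JSON and CSV", {
  js <- withr::local_tempfile(fileext = ".json")
  cs <- withr::local_tempfile(fileext = ".csv")
  fit <- run_titration_analysis(
    simulate_titration(make_titration_spec(12, c(0, 0),
                                           responder_delta = c(0.25, 1.1))),
    json = js, csv = cs)
  rep <- jsonlite::read_json(js)
  expect_equal(rep$kd_mean, fit$kd_mean, tolerance = 1e-9)
  expect_equal(rep$n_retained, fit$n_retained)
  tab <- read.csv(cs)
  expect_equal(nrow(tab), nrow(fit$fits))
})

test_that("the global shared-Kd extension agrees on noiseless data", {
  spec <- make_titration_spec(12, c(0, 0),
                              responder_delta = c(0.25, 1.1))
  fit <- fit_titration(simulate_titration(spec), global = TRUE)
  expect_equal(fit$global_fit$kd, 12, tolerance = 1e-3)
})
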