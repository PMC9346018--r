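# Stress metrics: threshold semantics, area weighting, VMes interface stats,
# alignment indices.

test_that("pressure statistics apply the inclusion threshold correctly", {
  psv <- patellofem:::pressure_stats_values
  u <- psv(rep(0.5, 50), rep(2, 50), tau = 0.271)
  expect_equal(u$peak, 0.5)
  expect_equal(u$mean, 0.5)
  two <- psv(c(0.2, 0.8), c(1, 1), tau = 0.271)
  expect_equal(two$peak, 0.8)
  expect_equal(two$mean, 0.8)        # 0.2 excluded by the 271 kPa rule
  w <- psv(c(0.3, 0.4, 0.5), c(1, 1, 2), tau = 0.271)
  expect_equal(w$mean, (0.3 + 0.4 + 1.0) / 4)
  none <- psv(c(0.1, 0.2), c(1, 1), tau = 0.271)
  expect_true(is.na(none$mean))      # absent, not zero
  expect_equal(none$peak, 0.2)
})

test_that("raising tau never grows the included set nor lowers the mean", {
  psv <- patellofem:::pressure_stats_values
  set.seed(11)
  p <- runif(200, 0, 2); a <- runif(200, 0.5, 2)
  taus <- c(0, 0.1, 0.271, 0.5, 1.0)
  res <- lapply(taus, function(t) psv(p, a, t))
  ns <- vapply(res, `[[`, numeric(1), "n_faces_included")
  ms <- vapply(res, `[[`, numeric(1), "mean")
  expect_true(all(diff(ns) <= 0))
  expect_true(all(diff(ms) >= -1e-12))
})

test_that("solution metrics: thresholded pressures and tau-invariant area", {
  res <- solved_healthy_45()
  ps <- pressure_stats(res$sol, res$sys)
  expect_gte(ps$peak, ps$mean)
  expect_gte(ps$mean, STRESS_TAU)
  a0 <- contact_area(res$sol, res$sys)
  a_tau <- contact_area(res$sol, res$sys, tau = STRESS_TAU)
  expect_gt(a0, 0)
  # generator calibration band: healthy contact area of order 600 mm^2
  expect_gte(a0, 500)
  expect_lte(a0, 750)
  expect_gte(a0, a_tau)              # the tau variant can only shrink it
  # area is invariant to the reporting threshold tau
  expect_identical(contact_area(res$sol, res$sys), a0)
  # refusal on unconverged solutions
  bad <- res$sol; bad$converged <- FALSE
  expect_error(pressure_stats(bad, res$sys), "did not converge")
})

test_that("VMes interface statistics are available on all four interfaces", {
  res <- solved_healthy_45()
  for (region in c("patella", "trochlea")) {
    for (surf in c("articular", "bone_interface")) {
      v <- vmes_stats(res$sol, res$sys, region, surf)
      expect_gt(v$peak, 0)
      expect_true(is.na(v$mean) || v$mean <= v$peak)
    }
  }
  expect_error(vmes_stats(res$sol, res$sys, "femur"), "'arg' should be")
})

test_that("alignment indices: trivial poses give the textbook values", {
  h <- healthy_knee()
  pl <- h$patella_landmarks_local
  ax <- pl$most_lateral_patellar_point - pl$medial_patellar_edge_midpoint
  a0 <- patellofem:::rad2deg(atan2(-ax[2], ax[1]))
  # rotation canceling the intrinsic axis obliquity: tilt reads 0
  pose0 <- list(translation = c(0, 10, 0), tilt_deg = -a0)
  expect_close(patellar_tilt(h, pose0), 0, 1e-9)
  # symmetric placement about the sulcus plane: bisect offset 50%
  lat <- pose_points(pose0, pl$most_lateral_patellar_point)
  med <- pose_points(pose0, pl$medial_patellar_edge_midpoint)
  width <- lat[1] - med[1]
  pose50 <- pose0
  pose50$translation[1] <- -(med[1] + width / 2)
  expect_close(bisect_offset(h, pose50), 50, 1e-6)
  # TT-TG is the lateral offset of the tuberosity from the deepest sulcus
  expect_close(tt_tg(h), h$params$tt_tg, 0.5)
  broken <- h
  broken$landmarks$tibial_tuberosity_reference <- NULL
  expect_error(tt_tg(broken), "tibial_tuberosity_reference")
})

test_that("postoperative TT-TG measured by metrics drops by f * L_mean", {
  d <- dysplastic_knee()
  for (f in c(0.5, 1.5)) {
    r <- apply_trochleoplasty(d, surgery_params(f = f))
    expect_close(tt_tg(d) - tt_tg(r$model), f * 6.1, 0.5)
  }
})
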