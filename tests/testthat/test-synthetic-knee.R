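# Synthetic knee geometry: shell integrity, preset morphology, landmarks,
# determinism, mirroring.

test_that("generated shells are watertight with a single cartilage patch", {
  for (preset in c("healthy", "dysplastic_D")) {
    m <- if (preset == "healthy") healthy_knee() else dysplastic_knee()
    for (mesh in list(m$femur_surface, m$patella_surface)) {
      expect_true(is_watertight(mesh))
      expect_gt(patellofem:::shell_signed_volume(mesh$vertices, mesh$triangles), 0)
      expect_true(all(triangle_areas(mesh) > 1e-9))
      expect_equal(patellofem:::cartilage_patch_count(mesh), 1L)
    }
  }
})

test_that("healthy preset grooves everywhere; type-D flat/convex proximally", {
  h <- healthy_knee()
  expect_true(all(h$depths > 0))
  d <- dysplastic_knee()
  expect_lte(d$depths[length(d$depths)], 0)   # proximal-most station
  expect_gt(max(d$depths), 0)                 # still grooved mid-trochlea
})

test_that("dysplastic preset exceeds healthy in TT-TG and bisect target", {
  h <- healthy_knee(); d <- dysplastic_knee()
  expect_close(tt_tg(d), 17, 0.6)   # study knee: TT-TG 17 mm
  expect_gt(tt_tg(d), tt_tg(h))
  expect_equal(h$alignment$bisect_target, 48.5)  # healthy bisect offset 48.5%
  expect_gt(d$alignment$bisect_target, h$alignment$bisect_target)
  # the placed pose realizes the configured bisect target
  pose_h <- place_patella(h, 45)
  expect_close(bisect_offset(h, pose_h), 48.5, 0.1)
  pose_d <- place_patella(d, 45)
  expect_close(bisect_offset(d, pose_d), 76, 0.1)
  expect_close(patellar_tilt(h, pose_h), 12, 1e-6)
  expect_close(patellar_tilt(d, pose_d), 18, 1e-6)
})

test_that("generation is deterministic and seed-independent without jitter", {
  a <- build_knee("healthy", resolution = 0.35, seed = 1)
  b <- build_knee("healthy", resolution = 0.35, seed = 2)
  expect_identical(a$femur_surface$vertices, b$femur_surface$vertices)
  expect_identical(a$landmarks, b$landmarks)
  # jitter is seeded and reproducible
  j1 <- build_knee("healthy", overrides = list(jitter = 0.05),
                   resolution = 0.35, seed = 3)
  j2 <- build_knee("healthy", overrides = list(jitter = 0.05),
                   resolution = 0.35, seed = 3)
  j3 <- build_knee("healthy", overrides = list(jitter = 0.05),
                   resolution = 0.35, seed = 4)
  expect_identical(j1$femur_surface$vertices, j2$femur_surface$vertices)
  expect_false(identical(j1$femur_surface$vertices, j3$femur_surface$vertices))
})

test_that("watertightness holds across random jitter seeds", {
  for (seed in 1:8) {
    m <- build_knee("dysplastic_D", overrides = list(jitter = 0.03),
                    resolution = 0.3, seed = seed)
    expect_true(is_watertight(m$femur_surface))
    expect_true(is_watertight(m$patella_surface))
  }
})

test_that("mirroring twice is the identity and mirrors landmarks exactly", {
  m <- healthy_knee()
  lm <- mirror_knee(m)
  expect_equal(lm$side, "left")
  expect_equal(lm$landmarks$LC[1], -m$landmarks$LC[1])
  expect_equal(lm$landmarks$LC[2:3], m$landmarks$LC[2:3])
  back <- mirror_knee(lm)
  expect_identical(back$femur_surface$vertices, m$femur_surface$vertices)
  expect_identical(back$femur_surface$triangles, m$femur_surface$triangles)
  expect_identical(back$landmarks, m$landmarks)
})

test_that("unknown overrides and invalid parameters are rejected with context", {
  expect_error(build_knee("healthy", overrides = list(nope = 1)),
               "valid keys")
  expect_error(dysplasia_params(sulcus_depth = 99), "sulcus_depth")
  expect_error(generate_trochlea(dysplasia_params(), n_stations = 3),
               "n_stations")
})

test_that("patella is sized to the trochlea and shifts its outline laterally", {
  tro <- generate_trochlea(dysplasia_params(), resolution = 0.4)
  expect_error(generate_patella(patella_params(width_med = 28, width_lat = 28), tro),
               "exceeds the trochlear bounding box")
  p0 <- generate_patella(patella_params(), tro, resolution = 0.4)
  p2 <- generate_patella(patella_params(ridge_x_offset = 2), tro, resolution = 0.4)
  d <- p2$landmarks$most_lateral_patellar_point -
    p0$landmarks$most_lateral_patellar_point
  expect_close(d[1], 2, 1e-9)  # +2 mm along the baseline direction
  expect_close(d[3], 0, 1e-9)
})

test_that("placement respects the configured clearance (no initial overlap)", {
  h <- healthy_knee()
  pose <- place_patella(h, 45)
  gap <- patellofem:::patellar_surface_gap(h, pose)
  expect_close(gap, 0.3, 0.05)
  expect_gte(gap, 0)
})
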