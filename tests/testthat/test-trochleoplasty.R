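# Virtual trochleoplasty: the Fig-style sulcus relocation, plane location,
# identity/locality/linearity invariants, wedge monotonicity, TT-TG algebra.

test_that("sulcus relocation follows the baseline-aligned construction", {
  pr <- list(anchors = list(em = c(-22, 0), mc = c(-14, 6), s = c(0, 0),
                            lc = c(14, 6), el = c(22, 0)))
  expect_equal(new_sulcus_point(pr, 0, 0), c(0, 0))
  expect_equal(new_sulcus_point(pr, 3, 2), c(3, -2))   # +x lateral, -y posterior
  expect_equal(new_sulcus_point(pr, 6.1 * 1.5, 0)[1], 9.15)
  expect_error(new_sulcus_point(pr, 15, 0), "beyond the condylar peaks")
  expect_error(new_sulcus_point(pr, 0, 30), "bone stock")
})

test_that("TT-TG change is linear in the correction factor", {
  expect_equal(tt_tg_change(surgery_params(f = 0.5)), 3.05)
  expect_equal(tt_tg_change(surgery_params(f = 1.5)), 9.15)
  expect_equal(tt_tg_change(surgery_params(f = 0)), 0)
})

test_that("correction planes bracket the articulating groove", {
  d <- dysplastic_knee()
  pl <- locate_correction_planes(d)
  expect_lt(pl$distal_z, pl$proximal_z)
  # default 45 deg threshold: planes span >= 60% of the sulcus polyline
  sp <- d$landmarks$sulcus_polyline
  seg_len <- sqrt(rowSums(diff(sp)^2))
  zmid <- (sp[-1, 3] + sp[-nrow(sp), 3]) / 2
  inside <- zmid >= pl$distal_z & zmid <= pl$proximal_z
  expect_gte(sum(seg_len[inside]) / sum(seg_len), 0.6)
  # threshold 90 deg: distal plane at the distal end of the polyline
  pl90 <- locate_correction_planes(d, notch_angle = 90)
  expect_equal(pl90$distal_z, min(sp[, 3]))
  # uniform cartilage coverage: proximal plane at the patch margin station
  u <- build_knee("healthy", resolution = 0.4,
                  overrides = list())
  u$femur_surface$region <- ifelse(
    seq_len(nrow(u$femur_surface$vertices)) %in%
      unlist(lapply(u$profiles, function(p) p$arc_ids)),
    "cartilage", "bone")
  plu <- locate_correction_planes(u)
  zs <- vapply(u$profiles, `[[`, numeric(1), "z")
  expect_equal(plu$proximal_z, max(zs))
})

test_that("zero correction is the exact identity", {
  d <- dysplastic_knee()
  r <- apply_trochleoplasty(d, surgery_params(f = 0))
  expect_identical(r$model$femur_surface$vertices, d$femur_surface$vertices)
  expect_equal(r$wedge_volume, 0)
  expect_equal(max(r$displacement), 0)
})

test_that("displacement is local to the correction band on the anterior arc", {
  d <- dysplastic_knee()
  r <- apply_trochleoplasty(d, surgery_params(f = 1))
  pl <- r$planes
  arc_ids <- unlist(lapply(d$profiles, function(p) p$arc_ids))
  post_ids <- setdiff(seq_len(nrow(d$femur_surface$vertices)), arc_ids)
  expect_equal(max(r$displacement[post_ids]), 0)  # posterior condyles untouched
  z <- d$femur_surface$vertices[, 3]
  blend <- r$params$blend
  outside <- which(z < pl$distal_z - blend - 1e-9 | z > pl$proximal_z + blend + 1e-9)
  expect_equal(max(r$displacement[outside]), 0)
  # maximum displacement sits on the groove
  imax <- which.max(r$displacement)
  expect_lt(abs(d$femur_surface$vertices[imax, 1] -
                  deepest_sulcus_point(d)[1]), 8)
})

test_that("sulcus displacement equals f*(L, D) inside the band (linearity)", {
  d <- dysplastic_knee()
  for (f in c(0.5, 1, 1.5)) {
    r <- apply_trochleoplasty(d, surgery_params(f = f))
    zs <- vapply(d$profiles, `[[`, numeric(1), "z")
    inside <- which(zs >= r$planes$distal_z + 1e-9 & zs <= r$planes$proximal_z - 1e-9)
    for (k in inside) {
      dS <- r$model$profiles[[k]]$anchors$s - d$profiles[[k]]$anchors$s
      expect_close(dS[1], f * 6.1, 1e-9)
      expect_close(dS[2], -f * 4.0, 1e-9)
    }
  }
})

test_that("cartilage thickness is preserved by the flap remap", {
  d <- dysplastic_knee()
  r <- apply_trochleoplasty(d, surgery_params(f = 1.5))
  cart <- d$femur_surface$region == "cartilage"
  expect_lt(max(abs(r$model$femur_thickness[cart] - d$femur_thickness[cart])),
            1e-3)
  expect_identical(r$model$femur_surface$region, d$femur_surface$region)
})

test_that("wedge volume grows strictly with the correction factor", {
  d <- dysplastic_knee()
  v <- vapply(c(0.5, 1, 1.5), function(f) {
    apply_trochleoplasty(d, surgery_params(f = f))$wedge_volume
  }, numeric(1))
  expect_true(all(diff(v) > 0))
  expect_gt(v[1], 0)
})

test_that("postoperative TT-TG drops by tt_tg_change within 0.5 mm", {
  d <- dysplastic_knee()
  for (f in c(0.5, 1, 1.5)) {
    p <- surgery_params(f = f)
    r <- apply_trochleoplasty(d, p)
    expect_close(tt_tg(d) - tt_tg(r$model), tt_tg_change(p), 0.5)
  }
})

test_that("straight-segment mode produces the literal two-segment groove", {
  d <- dysplastic_knee()
  r <- apply_trochleoplasty(d, surgery_params(f = 1, straight_segments = TRUE))
  k0 <- which.max(d$depths)
  pr <- r$model$profiles[[k0]]
  a <- pr$anchors
  mid <- pr$arc_x > a$mc[1] + 0.1 & pr$arc_x < a$s[1] - 0.1
  # points between MC and S1 lie on the MC-S1 chord, away from the
  # smooth-min junction with the untouched surface (blend scale 0.3 mm)
  yl <- a$mc[2] + (a$s[2] - a$mc[2]) * (pr$arc_x[mid] - a$mc[1]) / (a$s[1] - a$mc[1])
  old_fun <- patellofem:::arc_y_fun(d$profiles[[k0]]$anchors)
  deep <- old_fun(pr$arc_x[mid]) - yl > 1
  expect_gte(sum(deep), 3)
  # the 0.3 mm smooth-min junction leaves an O(k e^(-depth/k)) trace, about
  # 0.01 mm at 1 mm of resection and vanishing deeper in
  expect_lt(max(abs(pr$arc_y[mid][deep] - yl[deep])), 0.02)
})
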