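# Contact detection: gaps, penetration sign convention, sphere-plane
# geometry, determinism.

grid_patch <- function(n = 10, L = 10, y = 0) {
  xs <- seq(-L / 2, L / 2, length.out = n + 1)
  g <- expand.grid(x = xs, z = xs)
  verts <- cbind(g$x, y, g$z)
  id <- function(i, j) (j - 1L) * (n + 1L) + i
  # wound so that triangle normals face +y
  tris <- do.call(rbind, lapply(seq_len(n), function(j) {
    do.call(rbind, lapply(seq_len(n), function(i) {
      rbind(c(id(i, j), id(i + 1, j + 1), id(i + 1, j)),
            c(id(i, j), id(i, j + 1), id(i + 1, j + 1)))
    }))
  }))
  list(verts = verts, tris = tris)
}

test_that("parallel flat patches report uniform signed gaps", {
  master <- grid_patch(8, 10, y = 0)  # normal +y
  slave <- grid_patch(6, 8, y = 1)$verts
  det <- detect_contact(slave, master$verts, master$tris)
  expect_true(all(abs(det$penetration + 1) < 1e-12))  # gap -1 = 1 mm open
  expect_false(any(det$active))
  # displaced 1.5 mm into the master: +0.5 mm penetration everywhere
  slave2 <- slave; slave2[, 2] <- slave2[, 2] - 1.5
  det2 <- detect_contact(slave2, master$verts, master$tris)
  expect_true(all(abs(det2$penetration - 0.5) < 1e-12))
  expect_true(all(det2$active))
})

test_that("sphere-into-plane active set matches the interpenetration circle", {
  master <- grid_patch(40, 20, y = 0)
  # sphere R = 10 dipped delta = 0.1 below the plane
  R <- 10; delta <- 0.1
  th <- seq(0, 2 * pi, length.out = 200)[-1]
  rr <- seq(0, 3, by = 0.1)
  pts <- do.call(rbind, lapply(rr, function(r) {
    if (r > sqrt(max(0, R^2 - (R - delta)^2))) return(NULL)
    y <- (R - delta) - sqrt(R^2 - r^2)  # sphere surface height
    cbind(r * cos(th), y, r * sin(th))
  }))
  det <- detect_contact(pts, master$verts, master$tris)
  act_r <- sqrt(pts[det$node[det$active], 1]^2 + pts[det$node[det$active], 3]^2)
  a_pred <- sqrt(2 * R * delta)  # contact circle of sphere-plane overlap
  edge <- 20 / 40  # one mesh edge length
  expect_lt(max(act_r), a_pred + edge)
  expect_gt(max(act_r), a_pred - edge)
})

test_that("detection is deterministic and robust to degenerate queries", {
  h <- healthy_knee()
  pose <- place_patella(h, 45)
  pv <- pose_points(pose, h$patella_surface$vertices)
  cart <- h$patella_surface$region == "cartilage"
  tris <- h$femur_surface$triangles[patellofem:::cartilage_triangles(h$femur_surface), ]
  g1 <- point_surface_gaps(pv[cart, ], h$femur_surface$vertices, tris)
  g2 <- point_surface_gaps(pv[cart, ], h$femur_surface$vertices, tris)
  expect_identical(g1, g2)
  # far-away points simply find no candidates
  far <- matrix(c(500, 500, 500), 1)
  gf <- point_surface_gaps(far, h$femur_surface$vertices, tris)
  expect_true(is.infinite(gf$gap))
})

test_that("closest-point projection handles vertex/edge/face regions exactly", {
  a <- matrix(c(0, 0, 0), 1); b <- matrix(c(1, 0, 0), 1); c_ <- matrix(c(0, 1, 0), 1)
  cp <- function(p) patellofem:::closest_point_pairs(matrix(p, 1), a, b, c_)$point
  expect_equal(as.numeric(cp(c(-1, -1, 0))), c(0, 0, 0))        # vertex a
  expect_equal(as.numeric(cp(c(2, 0.5, 0))), c(1, 0, 0))        # vertex b
  expect_equal(as.numeric(cp(c(0.5, -1, 0))), c(0.5, 0, 0))     # edge ab
  expect_equal(as.numeric(cp(c(0.25, 0.25, 5))), c(0.25, 0.25, 0))  # interior
  expect_equal(as.numeric(cp(c(1, 1, 0))), c(0.5, 0.5, 0))      # edge bc
})
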