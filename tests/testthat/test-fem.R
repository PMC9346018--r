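# Cartilage extrusion and linear-elastic tetrahedral discretization.

flat_patch <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(1, 0, 1), c(0, 0, 1)),
               rbind(c(1, 2, 3), c(1, 3, 4)),
               region = rep("cartilage", 4))
}

test_that("prism extrusion produces the expected tet and node counts", {
  tm <- extrude_cartilage(flat_patch(), rep(1, 4), layers = 1)
  expect_equal(nrow(tm$tets), 6)
  expect_equal(nrow(tm$nodes), 8)
  tm3 <- extrude_cartilage(flat_patch(), rep(1, 4), layers = 3)
  expect_equal(nrow(tm3$tets) / nrow(tm$tets), 3)
  # conforming positive-volume mesh filling thickness x area exactly
  expect_true(all(tet_volumes(tm$nodes, tm$tets) > 0) ||
                all(tm$volumes > 0))
  expect_equal(sum(tm$volumes), 1, tolerance = 1e-12)
  # node sets partition the boundary correctly
  expect_equal(tm$node_sets$articular_surface, 1:4)
  expect_equal(tm$node_sets$bone_interface, 5:8)
})

test_that("knee fixture extrusion brackets the study's deformable element count", {
  h <- fixture("count_knee", function() build_knee("healthy", resolution = 1))
  fem <- extrude_cartilage(h$femur_surface, h$femur_thickness, layers = 2)
  pat <- extrude_cartilage(h$patella_surface, h$patella_thickness, layers = 2)
  total <- nrow(fem$tets) + nrow(pat$tets)
  expect_gte(total, 20000)
  expect_lte(total, 60000)
})

test_that("thickness scaling is the documented sensitivity envelope", {
  m <- rep(3, 5)
  expect_equal(scale_thickness(m, 1.0), m)
  expect_equal(scale_thickness(m, 0.6), rep(1.8, 5))
  expect_equal(scale_thickness(scale_thickness(m, 1.4), 1 / 1.4), m,
               tolerance = 1e-12)
  expect_error(scale_thickness(m, 1.5), "factor")
  expect_error(scale_thickness(m, 0.5), "factor")
})

test_that("assembled stiffness is symmetric with six rigid-body modes", {
  mesh <- box_tet_mesh(2, 2, 2, 1, 1, 1)
  m <- material_params()
  K <- assemble_stiffness(mesh, m)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-10 * max(abs(K)))
  n <- nrow(mesh$nodes)
  # translations and linearized rotations produce zero force
  modes <- list(rep(c(1, 0, 0), n), rep(c(0, 1, 0), n), rep(c(0, 0, 1), n))
  x <- mesh$nodes
  rots <- list(as.vector(t(cbind(-x[, 2], x[, 1], 0))),
               as.vector(t(cbind(0, -x[, 3], x[, 2]))),
               as.vector(t(cbind(x[, 3], 0, -x[, 1]))))
  for (v in c(modes, rots)) {
    expect_lt(max(abs(K %*% v)), 1e-9 * max(abs(K)))
  }
  ev <- eigen(as.matrix(K), symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(ev < 1e-8 * max(ev)), 6)
})

test_that("element stiffness matches the assembled one-element system", {
  nodes <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  m <- material_params()
  K1 <- element_stiffness(nodes, m)
  mesh1 <- structure(list(nodes = nodes, tets = matrix(1:4, 1)),
                     class = "tet_mesh")
  K2 <- as.matrix(assemble_stiffness(mesh1, m))
  expect_equal(K1, K2, tolerance = 1e-12, ignore_attr = TRUE)
  expect_error(element_stiffness(nodes[c(1, 3, 2, 4), ], m), "[Ii]nverted")
})

test_that("patch test: affine fields reproduced to machine precision", {
  mesh <- box_tet_mesh(3, 2, 2, 2, 1.5, 1)
  expect_lt(patch_test(mesh, material_params()), 1e-10)
  expect_lt(patch_test(mesh, material_params(E = 12, nu = 0.3)), 1e-10)
})

test_that("confined compression reproduces the constrained modulus closed form", {
  m <- material_params()  # E = 5.0, nu = 0.47
  cc <- confined_compression(m, strain = 0.01)
  expect_equal(cc$expected_sigma, -0.300453, tolerance = 1e-4)
  expect_lt(abs(cc$sigma_axial - cc$expected_sigma) / abs(cc$expected_sigma), 1e-3)
  # VMes under confined compression: |sigma| (1-2nu)/(1-nu)
  expect_lt(abs(cc$vmes - cc$expected_vmes) / cc$expected_vmes, 1e-3)
})

test_that("element stress closed forms: hydrostatic and uniaxial VMes", {
  # pure hydrostatic strain: VMes = 0
  sig_h <- matrix(c(2, 2, 2, 0, 0, 0), 1)
  expect_equal(von_mises(sig_h), 0)
  # uniaxial stress sigma: VMes = |sigma|
  sig_u <- matrix(c(-1.7, 0, 0, 0, 0, 0), 1)
  expect_equal(von_mises(sig_u), 1.7)
  # hydrostatic offset invariance
  set.seed(1)
  s <- matrix(rnorm(60), 10)
  off <- s; off[, 1:3] <- off[, 1:3] + 5
  expect_equal(von_mises(s), von_mises(off), tolerance = 1e-12)
})
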