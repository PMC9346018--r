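# Mesh I/O round-trips and error paths.

tet_surface <- function() {
  surface_mesh(rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1)),
               rbind(c(1, 3, 2), c(1, 2, 4), c(2, 3, 4), c(1, 4, 3)),
               region = c("bone", "bone", "cartilage", "cartilage"))
}

test_that("PLY round-trip preserves topology, coordinates and labels", {
  m <- tet_surface()
  f <- tempfile(fileext = ".ply")
  write_mesh(m, f)
  r <- read_mesh(f)
  expect_equal(r$vertices, m$vertices, tolerance = 1e-9)
  expect_identical(r$triangles, m$triangles)
  expect_identical(r$region, m$region)
  # knee-preset round trip: identical topology, coordinates within 1e-6 mm
  k <- healthy_knee()
  f2 <- tempfile(fileext = ".ply")
  write_mesh(k$femur_surface, f2)
  r2 <- read_mesh(f2)
  expect_identical(r2$triangles, k$femur_surface$triangles)
  expect_lt(max(abs(r2$vertices - k$femur_surface$vertices)), 1e-6)
  expect_identical(r2$region, k$femur_surface$region)
})

test_that("landmark JSON sidecar round-trips points and polylines", {
  k <- healthy_knee()
  f <- tempfile(fileext = ".json")
  write_landmarks(k$landmarks, f)
  r <- read_landmarks(f)
  expect_equal(names(r), names(k$landmarks))
  expect_equal(r$LC, k$landmarks$LC, tolerance = 1e-12)
  expect_equal(dim(r$sulcus_polyline), dim(k$landmarks$sulcus_polyline))
})

test_that("STL ascii and binary round-trip geometry; labels dropped with warning", {
  m <- tet_surface()
  fa <- tempfile(fileext = ".stl")
  expect_warning(write_mesh(m, fa), "labels dropped")
  ra <- read_mesh(fa)
  expect_equal(nrow(ra$vertices), 4)
  expect_equal(nrow(ra$triangles), 4)
  expect_true(all(ra$region == "bone"))
  expect_equal(sort(ra$vertices[, 1]), sort(m$vertices[, 1]), tolerance = 1e-6)

  fb <- tempfile(fileext = ".stl")
  expect_warning(write_mesh(m, fb, format = "stl_binary"), "labels dropped")
  rb <- read_mesh(fb)
  expect_equal(nrow(rb$vertices), 4)
  expect_equal(nrow(rb$triangles), 4)
  # same enclosed volume either way
  v0 <- patellofem:::shell_signed_volume(m$vertices, m$triangles)
  expect_equal(abs(patellofem:::shell_signed_volume(rb$vertices, rb$triangles)),
               abs(v0), tolerance = 1e-5)
})

test_that("OFF round-trips and rejects non-triangle faces with the face index", {
  m <- tet_surface()
  f <- tempfile(fileext = ".off")
  suppressWarnings(write_mesh(m, f))
  r <- read_mesh(f)
  expect_equal(nrow(r$vertices), 4)
  expect_identical(r$triangles, m$triangles)
  quad <- c("OFF", "4 1 0", "0 0 0", "1 0 0", "1 1 0", "0 1 0", "4 0 1 2 3")
  fq <- tempfile(fileext = ".off")
  writeLines(quad, fq)
  expect_error(read_mesh(fq), "face 1")
})

test_that("malformed files and missing paths raise parse errors", {
  expect_error(read_mesh(tempfile(fileext = ".ply")), "does not exist")
  f <- tempfile(fileext = ".ply")
  writeLines(c("ply", "format ascii 1.0"), f)
  expect_error(read_mesh(f), "end_header")
  fs <- tempfile(fileext = ".stl")
  writeLines(c("solid x", "facet", " vertex 1 2", "endsolid"), fs)
  expect_error(read_mesh(fs), "malformed")
})
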