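# Load-case construction: muscle split, springs, prestrain algebra,
# flexion-angle handling.

test_that("quadriceps split is proportional to the reported group forces", {
  expect_equal(muscle_components(276), c(RF_VI = 111, VM = 67, VL = 98))
  expect_equal(unname(muscle_components(0)), c(0, 0, 0))
  expect_equal(muscle_components(552), c(RF_VI = 222, VM = 134, VL = 196))
  expect_equal(sum(muscle_components(100)), 100, tolerance = 1e-12)
  # proportions invariant under scaling
  expect_equal(muscle_components(100) / 100, muscle_components(1),
               tolerance = 1e-12)
  expect_error(muscle_components(-1), ">= 0")
})

test_that("spring force follows Hooke with tension-only clamping", {
  s <- spring_element(c(0, 0, 0), c(10, 0, 0), k = 6.45, rest_length = 10)
  f <- spring_force(s, c(0, 0, 0), c(12, 0, 0))
  expect_equal(f$tension, 12.9)
  expect_equal(f$f_insertion, c(-12.9, 0, 0))
  expect_equal(f$f_origin + f$f_insertion, c(0, 0, 0))  # Newton's third law
  slack <- spring_force(s, c(0, 0, 0), c(9, 0, 0))
  expect_equal(slack$tension, 0)
  expect_equal(slack$f_insertion, c(0, 0, 0))
  bil <- spring_element(c(0, 0, 0), c(10, 0, 0), k = 2, rest_length = 10,
                        tension_only = FALSE)
  expect_equal(spring_force(bil, c(0, 0, 0), c(9, 0, 0))$tension, -2)
  expect_error(spring_force(s, c(1, 1, 1), c(1, 1, 1)), "coincide")
})

test_that("prestrain sets the rest length so force = k L eps/(1+eps)", {
  L <- 37.5; eps <- 0.02; k <- 6.45
  s <- spring_element(c(0, 0, 0), c(L, 0, 0), k = k, prestrain = eps)
  expect_equal(s$rest_length, L / (1 + eps))
  f <- spring_force(s)
  expect_equal(f$tension, k * L * eps / (1 + eps), tolerance = 1e-12)
  s0 <- spring_element(c(0, 0, 0), c(L, 0, 0), k = k, prestrain = 0)
  expect_equal(spring_force(s0)$tension, 0)
})

test_that("load case carries the documented springs and muscle resultant", {
  h <- healthy_knee()
  case <- build_load_case(h, 45)
  expect_length(case$springs, 5)
  ks <- vapply(case$springs, `[[`, numeric(1), "k")
  expect_equal(sum(ks[1:3]), 4334)
  expect_equal(unname(ks[1:3]), rep(4334 / 3, 3))
  expect_equal(unname(ks[4:5]), c(6.45, 5.42))
  expect_equal(vnorm(case$muscle$force) <= case$muscle$total, TRUE)
  expect_equal(sum(case$muscle$components), 276)
  # direction rows are unit vectors
  expect_equal(unname(row_norms(case$muscle$directions)), rep(1, 3),
               tolerance = 1e-12)
  # zero prestrain: ligaments carry no force at the rest pose
  case0 <- build_load_case(h, 45, loading_config(prestrain = 0))
  for (nm in 4:5) {
    expect_equal(spring_force(case0$springs[[nm]])$tension, 0, tolerance = 1e-9)
  }
})

test_that("the compressive (posterior) quadriceps component grows with flexion", {
  h <- healthy_knee()
  post30 <- -build_load_case(h, 30)$muscle$force[2]
  post75 <- -build_load_case(h, 75)$muscle$force[2]
  expect_gt(post75, post30)
})

test_that("load case construction is pure and range-checked", {
  h <- healthy_knee()
  a <- build_load_case(h, 60)
  b <- build_load_case(h, 60)
  a$config <- b$config <- NULL
  expect_identical(a, b)
  expect_error(build_load_case(h, 90), "outside the configured range")
  expect_error(build_load_case(h, 10), "outside the configured range")
})
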