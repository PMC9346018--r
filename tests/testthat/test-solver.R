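# Quasi-static solver: equilibrium, convergence contract, determinism,
# penalty insensitivity, friction bounds.

test_that("zero load with positive clearance gives the trivial equilibrium", {
  h <- healthy_knee()
  case <- build_load_case(h, 45, loading_config(muscle_total = 0, prestrain = 0))
  sys <- build_fe_system(h, case, material_params(), layers = 1)
  # no seating offset: start exactly at the placed pose
  set0 <- solver_settings(n_ramp = 1)
  case$config$clearance <- -0.05  # seating heuristic overshoots by 0.05
  sys$case <- case
  sol <- solve_quasistatic(sys, set0)
  expect_true(sol$converged)
  expect_equal(sol$iterations, 0)
  expect_equal(max(abs(sol$u_full)), 0)
})

test_that("converged solutions satisfy the global force balance", {
  res <- solved_healthy_45()
  expect_true(res$sol$converged)
  rr <- residual_report(res$sol, res$sys)
  applied <- vnorm(rr$muscle)
  expect_lt(vnorm(rr$net) / applied, 2e-6)
  expect_lt(rr$relative_residual, 1e-6)
  # contact pressures are non-negative everywhere
  expect_gte(min(res$sol$contact$pressure), 0)
})

test_that("friction obeys the Coulomb bound; disabled friction is exactly zero", {
  res <- solved_healthy_45()
  mu <- res$sys$material$mu
  p <- res$sol$contact$pressure
  tmag <- row_norms(res$sol$contact$tangential)
  expect_true(all(tmag <= mu * p + 1e-9))
  setf <- solver_settings(friction_enabled = FALSE)
  solf <- solve_quasistatic(res$sys, setf)
  expect_true(solf$converged)
  expect_equal(max(row_norms(solf$contact$tangential)), 0)
})

test_that("solves are bitwise deterministic across reruns", {
  res <- solved_healthy_45()
  s2 <- solve_quasistatic(res$sys, res$sol$settings)
  expect_identical(res$sol$q, s2$q)
  expect_identical(res$sol$contact$pressure, s2$contact$pressure)
  expect_identical(res$sol$iterations, s2$iterations)
})

test_that("peak pressure is insensitive to the penalty stiffness", {
  res <- solved_healthy_45()
  p1 <- pressure_stats(res$sol, res$sys)$peak
  sol2 <- solve_quasistatic(res$sys,
                            solver_settings(penalty_stiffness = 2 * res$sol$settings$penalty_stiffness))
  expect_true(sol2$converged)
  p2 <- pressure_stats(sol2, res$sys)$peak
  expect_lt(abs(p2 - p1) / p1, 0.02)
})

test_that("residual penetration stays below 1% of local thickness", {
  res <- solved_healthy_45()
  pen <- res$sol$contact$penetration
  act <- pen > 0
  thick_loc <- res$sys$patella$nodes  # thickness at slave nodes
  h <- healthy_knee()
  tmap <- h$patella_thickness[res$sys$patella$surf_vertex_ids]
  q99 <- stats::quantile(pen[act] / tmap[act], 0.99)
  expect_lt(q99, 0.01)
})

test_that("augmented Lagrange drives penetration below the gap tolerance", {
  res <- solved_healthy_45()
  sal <- solve_quasistatic(res$sys,
                           solver_settings(formulation = "augmented_lagrange",
                                           al_outer = 4))
  expect_true(sal$converged)
  expect_lt(max(sal$contact$penetration), solver_settings()$al_gap_tol)
  # pressures agree with the penalty solve at the few-percent level
  expect_lt(abs(max(sal$contact$pressure) - max(res$sol$contact$pressure)) /
              max(res$sol$contact$pressure), 0.05)
})

test_that("mesh refinement changes peak pressure by less than 5%", {
  dr <- fixture("drift_pair", function() {
    h2 <- build_knee("healthy", resolution = 0.4 * sqrt(2))  # ~2x elements
    r2 <- solve_configuration(h2, 45, test_study_config(0.4 * sqrt(2)))
    list(coarse = solved_healthy_45()$metrics$peak_pressure,
         fine = r2$metrics$peak_pressure)
  })
  expect_lt(abs(dr$fine - dr$coarse) / dr$coarse, 0.05)
})
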