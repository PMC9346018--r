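# Shared low-resolution fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

fixture <- function(name, builder) {
  if (!exists(name, fixture_env)) assign(name, builder(), fixture_env)
  get(name, fixture_env)
}

healthy_knee <- function(res = 0.4) {
  fixture(paste0("healthy_", res), function() build_knee("healthy", resolution = res))
}

dysplastic_knee <- function(res = 0.4) {
  fixture(paste0("dys_", res), function() build_knee("dysplastic_D", resolution = res))
}

# a coarse study config for solver-based tests
test_study_config <- function(res = 0.4) {
  study_config(resolution = res,
               solver = solver_settings(newton_tol = 1e-6))
}

solved_healthy_45 <- function(res = 0.4) {
  fixture(paste0("sol_h45_", res), function() {
    solve_configuration(healthy_knee(res), 45, test_study_config(res))
  })
}

solved_dysplastic_45 <- function(res = 0.4) {
  fixture(paste0("sol_d45_", res), function() {
    solve_configuration(dysplastic_knee(res), 45, test_study_config(res))
  })
}

solved_dysplastic_30 <- function(res = 0.4) {
  fixture(paste0("sol_d30_", res), function() {
    solve_configuration(dysplastic_knee(res), 30, test_study_config(res))
  })
}

solved_postop_30 <- function(res = 0.4) {
  fixture(paste0("sol_p30_", res), function() {
    pm <- apply_trochleoplasty(dysplastic_knee(res), surgery_params(f = 1))$model
    solve_configuration(pm, 30, test_study_config(res))
  })
}

vnorm <- patellofem:::vnorm
row_norms <- patellofem:::row_norms

expect_close <- function(actual, expected, tol) {
  expect_true(abs(actual - expected) <= tol,
              label = sprintf("|%g - %g| <= %g", actual, expected, tol))
}
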