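# Study orchestration: plan, tables, determinism of the table layer,
# sensitivity driver wiring.

test_that("dry run lists the full 20-solve plan", {
  plan <- run_study(study_config(), dry_run = TRUE)
  expect_equal(nrow(plan), 20)  # (healthy + preop + 3 factors) x 4 angles
  expect_setequal(unique(plan$configuration),
                  c("healthy", "preop", "f0.5", "f1", "f1.5"))
  expect_setequal(unique(plan$theta), c(30, 45, 60, 75))
})

test_that("study tables recompute exactly from the metrics data frame", {
  # synthetic metrics: the table layer is pure arithmetic over it
  cfgs <- c("healthy", "preop", "f0.5", "f1", "f1.5")
  set.seed(5)
  metrics <- expand.grid(configuration = cfgs, theta = c(30, 45, 60, 75),
                         stringsAsFactors = FALSE)
  for (col in c("peak_pressure", "mean_pressure", "contact_area",
                "peak_vmes_patella", "mean_vmes_patella",
                "peak_vmes_trochlea", "mean_vmes_trochlea")) {
    metrics[[col]] <- round(runif(nrow(metrics), 0.5, 3), 3)
  }
  metrics$tilt <- 10; metrics$bisect_offset <- 50
  metrics$tt_tg <- ifelse(metrics$configuration == "healthy", 9, 15)
  tabs <- study_tables(metrics, study_config())
  w <- tabs$per_angle$peak_pressure
  expect_equal(w$theta, c(30, 45, 60, 75))
  # percent-change columns agree with the operator
  expect_equal(w$f1_pct, percent_change(w$f1, w$preop))
  # pooled rows agree with pool()/pool_postop()
  expect_equal(tabs$pooled$peak_pressure$healthy$mean_full, mean(w$healthy))
  expect_equal(tabs$pooled$peak_pressure$postop$mean_full,
               mean(unlist(w[c("f0.5", "f1", "f1.5")])))
  expect_equal(tabs$pooled$peak_pressure$postop$n, 12L)
  # t-tests agree with the operators
  tt <- tabs$tests$peak_pressure$healthy_vs_preop
  ref <- t_test(w$healthy, w$preop)
  expect_equal(tt$p_value, ref$p_value)
  # rerunning the table layer is bitwise identical
  expect_identical(tabs, study_tables(metrics, study_config()))
})

test_that("study table CSVs round-trip the per-angle values", {
  cfgs <- c("healthy", "preop", "f0.5", "f1", "f1.5")
  metrics <- expand.grid(configuration = cfgs, theta = c(30, 45, 60, 75),
                         stringsAsFactors = FALSE)
  for (col in c("peak_pressure", "mean_pressure", "contact_area",
                "peak_vmes_patella", "mean_vmes_patella",
                "peak_vmes_trochlea", "mean_vmes_trochlea")) {
    metrics[[col]] <- seq_len(nrow(metrics)) / 7
  }
  metrics$tilt <- 1; metrics$bisect_offset <- 2; metrics$tt_tg <- 3
  bundle <- structure(list(metrics = metrics,
                           tables = study_tables(metrics, study_config()),
                           manifest = list()), class = "study_bundle")
  dir <- tempfile()
  write_study_tables(bundle, dir)
  expect_true(file.exists(file.path(dir, "table_peak_pressure.csv")))
  rt <- utils::read.csv(file.path(dir, "table_peak_pressure.csv"))
  expect_equal(rt$healthy, bundle$tables$per_angle$peak_pressure$healthy)
  pooled <- utils::read.csv(file.path(dir, "table_pooled.csv"))
  expect_true(all(c("metric", "group", "mean", "sd", "n") %in% names(pooled)))
})

test_that("sensitivity driver solves the thickness envelope rows", {
  tab <- sensitivity_driver(
    fixture("postop_model", function() {
      apply_trochleoplasty(dysplastic_knee(), surgery_params(f = 1))$model
    }),
    factors = c(0.8, 1), theta = 30, config = test_study_config())
  expect_equal(nrow(tab), 2)
  expect_true(all(tab$converged))
  expect_true(all(is.finite(tab$peak_vmes_patella)))
  # the factor-1 row equals the unperturbed solve exactly
  base <- solved_postop_30()
  expect_equal(tab$peak_vmes_patella[tab$factor == 1],
               base$metrics$peak_vmes_patella)
})
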