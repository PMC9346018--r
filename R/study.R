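# End-to-end study driver: healthy and dysplastic knees, virtual surgery at
# three correction factors, quasi-static solves over the flexion range, and
# the table/statistics layer mirroring the study report.

#' Study configuration
#'
#' @param thetas flexion angles (deg).
#' @param factors surgery correction factors.
#' @param resolution mesh density of the knee models used for the solves
#'   (see the methods vignette for the choice).
#' @param layers cartilage element layers.
#' @param material a [material_params()].
#' @param loading a [loading_config()].
#' @param solver a [solver_settings()].
#' @param surgery base [surgery_params()] (its `f` is overridden per run).
#' @param tau stress inclusion threshold (MPa).
#' @param seed integer seed recorded in the manifest (geometry jitter is off
#'   by default, so runs are deterministic).
#' @return named list of class `study_config`.
#' @export
study_config <- function(thetas = c(30, 45, 60, 75), factors = c(0.5, 1, 1.5),
                         resolution = 0.5, layers = 2,
                         material = material_params(),
                         loading = loading_config(theta = thetas),
                         solver = solver_settings(),
                         surgery = surgery_params(),
                         tau = STRESS_TAU, seed = 1L) {
  structure(list(thetas = thetas, factors = factors, resolution = resolution,
                 layers = layers, material = material, loading = loading,
                 solver = solver, surgery = surgery, tau = tau, seed = seed),
            class = "study_config")
}

#' Solve one configuration at one flexion angle
#'
#' @param model a `knee_model`.
#' @param theta flexion angle (deg).
#' @param config a [study_config()].
#' @return list with `sol`, `sys`, `case`, `metrics` (one-row data frame).
#' @export
solve_configuration <- function(model, theta, config = study_config()) {
  case <- build_load_case(model, theta, config$loading)
  sys <- build_fe_system(model, case, config$material, config$layers)
  sol <- solve_quasistatic(sys, config$solver)
  if (!sol$converged && sol$s_reached > 0.7) {
    # deterministic continuation fallback: finer load ramp, groove-seeking
    # start (the nested equilibrium basin of an operated trochlea). Cells
    # whose load path folds early (below 70% load) are reported as failed
    # without burning the retry budget.
    retry <- config$solver
    retry$n_ramp <- 2L * config$solver$n_ramp
    retry$presettle_groove <- TRUE
    sol <- solve_quasistatic(sys, retry)
  }
  metrics <- if (sol$converged) {
    solution_metrics(sol, sys, model, config$tau)
  } else {
    data.frame(theta = theta, peak_pressure = NA_real_, mean_pressure = NA_real_,
               contact_area = NA_real_, peak_vmes_patella = NA_real_,
               mean_vmes_patella = NA_real_, peak_vmes_trochlea = NA_real_,
               mean_vmes_trochlea = NA_real_, peak_vmes_patella_bone = NA_real_,
               mean_vmes_patella_bone = NA_real_, peak_vmes_trochlea_bone = NA_real_,
               mean_vmes_trochlea_bone = NA_real_, tilt = NA_real_,
               bisect_offset = NA_real_, tt_tg = tt_tg(model),
               iterations = sol$iterations, converged = FALSE)
  }
  list(sol = sol, sys = sys, case = case, metrics = metrics)
}

#' Run the full virtual-trochleoplasty study
#'
#' Builds the healthy and dysplastic knee models, applies the virtual surgery
#' at each correction factor, solves every configuration at every flexion
#' angle, and assembles per-angle, percent-change, pooled and t-test tables
#' in the layout of the study report.
#'
#' @param config a [study_config()].
#' @param dry_run if `TRUE`, return the solve plan without solving.
#' @param keep_solutions keep the full `pf_solution` objects (memory!).
#' @param progress print one line per solve.
#' @return list of class `study_bundle`: `metrics` (long data frame),
#'   `tables`, `manifest`, and (optionally) `solutions`.
#' @export
run_study <- function(config = study_config(), dry_run = FALSE,
                      keep_solutions = FALSE, progress = interactive()) {
  plan <- expand.grid(configuration = c("healthy", "preop",
                                        paste0("f", config$factors)),
                      theta = config$thetas, stringsAsFactors = FALSE)
  if (dry_run) return(plan)

  healthy <- build_knee("healthy", resolution = config$resolution,
                        seed = config$seed)
  dys <- build_knee("dysplastic_D", resolution = config$resolution,
                    seed = config$seed)
  models <- list(healthy = healthy, preop = dys)
  surgery_reports <- list()
  for (f in config$factors) {
    sp <- config$surgery
    sp$f <- f
    ost <- apply_trochleoplasty(dys, sp)
    models[[paste0("f", f)]] <- ost$model
    surgery_reports[[paste0("f", f)]] <-
      list(f = f, planes = ost$planes, wedge_volume = ost$wedge_volume,
           tt_tg_change = tt_tg_change(sp),
           tt_tg_post = tt_tg(ost$model))
  }
  rows <- list()
  sols <- list()
  failures <- list()
  for (i in seq_len(nrow(plan))) {
    cfg_name <- plan$configuration[i]
    th <- plan$theta[i]
    key <- paste0(cfg_name, "_", th)
    res <- tryCatch(
      solve_configuration(models[[cfg_name]], th, config),
      error = function(e) e)
    if (inherits(res, "error")) {
      failures[[key]] <- conditionMessage(res)
      next
    }
    if (progress) {
      cat(sprintf("  %-8s theta %2d: %s, peak %.3f MPa, area %.0f mm^2\n",
                  cfg_name, th, res$sol$status,
                  res$metrics$peak_pressure, res$metrics$contact_area))
    }
    row <- cbind(configuration = cfg_name, res$metrics)
    rows[[key]] <- row
    if (keep_solutions) sols[[key]] <- res[c("sol", "sys", "case")]
  }
  metrics <- do.call(rbind, rows)
  rownames(metrics) <- NULL
  structure(list(
    metrics = metrics,
    tables = study_tables(metrics, config),
    surgery = surgery_reports,
    manifest = list(config = config, plan = plan, failures = failures,
                    models = lapply(models, function(m) m$preset)),
    solutions = if (keep_solutions) sols else NULL
  ), class = "study_bundle")
}

# wide per-angle table for one metric column
#' @noRd
metric_wide <- function(metrics, col) {
  cfgs <- unique(metrics$configuration)
  out <- data.frame(theta = sort(unique(metrics$theta)))
  for (cf in cfgs) {
    sub <- metrics[metrics$configuration == cf, c("theta", col)]
    out[[cf]] <- sub[match(out$theta, sub$theta), col]
  }
  out
}

#' Assemble the study tables from the long metrics data frame
#'
#' @param metrics long data frame from [run_study()].
#' @param config the study configuration.
#' @return list of data frames: per-angle tables with percent changes versus
#'   preoperative, pooled summary rows, and the test results.
#' @export
study_tables <- function(metrics, config = study_config()) {
  fac_cols <- paste0("f", config$factors)
  add_pct <- function(wide) {
    for (fc in fac_cols) {
      if (!fc %in% names(wide)) next
      wide[[paste0(fc, "_pct")]] <-
        ifelse(is.na(wide[[fc]]) | is.na(wide$preop), NA,
               percent_change(wide[[fc]], wide$preop))
    }
    wide
  }
  pooled_row <- function(wide, cols) {
    v <- unlist(wide[cols])
    if (anyNA(v) || length(v) < 2) return(NULL)
    pool(v)
  }
  tabs <- list()
  for (spec in list(c("peak_pressure", "peak contact pressure [MPa]"),
                    c("mean_pressure", "mean contact pressure [MPa]"),
                    c("contact_area", "contact area [mm^2]"),
                    c("peak_vmes_patella", "peak VMes patella [MPa]"),
                    c("mean_vmes_patella", "mean VMes patella [MPa]"),
                    c("peak_vmes_trochlea", "peak VMes trochlea [MPa]"),
                    c("mean_vmes_trochlea", "mean VMes trochlea [MPa]"))) {
    w <- add_pct(metric_wide(metrics, spec[1]))
    attr(w, "label") <- spec[2]
    tabs[[spec[1]]] <- w
  }
  pooled <- list()
  tests <- list()
  for (nm in names(tabs)) {
    w <- tabs[[nm]]
    pooled[[nm]] <- list(
      healthy = pooled_row(w, "healthy"),
      preop = pooled_row(w, "preop"),
      postop = pooled_row(w, intersect(fac_cols, names(w)))
    )
    if (!anyNA(unlist(w[c("healthy", "preop")])) &&
        all(fac_cols %in% names(w)) && !anyNA(unlist(w[fac_cols]))) {
      tests[[nm]] <- list(
        healthy_vs_preop = t_test(w$healthy, w$preop),
        preop_vs_postop = t_test(w$preop, unlist(w[fac_cols]), welch = TRUE)
      )
    }
  }
  alignment <- metric_wide(metrics, "tilt")
  alignment_b <- metric_wide(metrics, "bisect_offset")
  list(per_angle = tabs, pooled = pooled, tests = tests,
       tilt = alignment, bisect_offset = alignment_b,
       tt_tg = unique(metrics[, c("configuration", "tt_tg")]))
}

#' Write the study tables as CSV files
#'
#' @param bundle a `study_bundle`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_study_tables <- function(bundle, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.csv(bundle$metrics, file.path(dir, "metrics_long.csv"),
                   row.names = FALSE)
  for (nm in names(bundle$tables$per_angle)) {
    utils::write.csv(bundle$tables$per_angle[[nm]],
                     file.path(dir, paste0("table_", nm, ".csv")),
                     row.names = FALSE)
  }
  pooled <- bundle$tables$pooled
  pr <- do.call(rbind, lapply(names(pooled), function(nm) {
    do.call(rbind, lapply(names(pooled[[nm]]), function(g) {
      p <- pooled[[nm]][[g]]
      if (is.null(p)) return(NULL)
      data.frame(metric = nm, group = g, mean = p$mean, sd = p$sd, n = p$n)
    }))
  }))
  utils::write.csv(pr, file.path(dir, "table_pooled.csv"), row.names = FALSE)
  tests <- bundle$tables$tests
  tr <- do.call(rbind, lapply(names(tests), function(nm) {
    do.call(rbind, lapply(names(tests[[nm]]), function(cmp) {
      t <- tests[[nm]][[cmp]]
      data.frame(metric = nm, comparison = cmp, test = t$test,
                 t = t$t_statistic, df = t$degrees_of_freedom,
                 p = t$p_value)
    }))
  }))
  utils::write.csv(tr, file.path(dir, "table_tests.csv"), row.names = FALSE)
  invisible(dir)
}

#' Cartilage-thickness sensitivity sweep
#'
#' Re-solves one configuration with the trochlear cartilage thickness map
#' scaled by each factor (the study's +/-40% envelope) and reports the peak
#' equivalent stress at the patellar articular (chondro-chondral) surface,
#' alongside the peak at the chondro-osseous interfaces.
#'
#' @param model the `knee_model` to perturb (typically the operated
#'   dysplastic model).
#' @param factors thickness multipliers within `[0.6, 1.4]`.
#' @param theta flexion angle (deg), default 45.
#' @param config a [study_config()].
#' @return data frame with one row per factor (failed rows flagged).
#' @export
sensitivity_driver <- function(model, factors = c(0.6, 0.8, 1, 1.2, 1.4),
                               theta = 45, config = study_config()) {
  rows <- lapply(factors, function(fac) {
    m2 <- model
    m2$femur_thickness <- scale_thickness(model$femur_thickness, fac)
    res <- tryCatch(solve_configuration(m2, theta, config),
                    error = function(e) e)
    if (inherits(res, "error") || !res$sol$converged) {
      return(data.frame(factor = fac, peak_vmes_patella = NA_real_,
                        peak_vmes_patella_bone = NA_real_,
                        peak_vmes_trochlea_bone = NA_real_,
                        peak_pressure = NA_real_, converged = FALSE))
    }
    data.frame(factor = fac,
               peak_vmes_patella = res$metrics$peak_vmes_patella,
               peak_vmes_patella_bone = res$metrics$peak_vmes_patella_bone,
               peak_vmes_trochlea_bone = res$metrics$peak_vmes_trochlea_bone,
               peak_pressure = res$metrics$peak_pressure, converged = TRUE)
  })
  do.call(rbind, rows)
}
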