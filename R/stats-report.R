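# Summary statistics and comparisons for the study tables: per-angle pooling,
# percent changes, Student/Welch t-tests (raw samples or summary statistics).

#' Pool per-angle values into a summary row
#'
#' Arithmetic mean and sample SD (divisor n-1), rounded half-away-from-zero
#' to two decimals as printed in the study tables; the unrounded values are
#' kept as `mean_full` / `sd_full`.
#'
#' @param values numeric vector (n >= 2).
#' @return list of class `summary_row` with `mean`, `sd`, `n`, `mean_full`,
#'   `sd_full`.
#' @export
pool <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || anyNA(values)) {
    pf_stop("pool() needs at least two non-missing values (sample SD undefined)")
  }
  m <- mean(values); s <- stats::sd(values)
  structure(list(mean = round_half_away(m, 2), sd = round_half_away(s, 2),
                 n = length(values), mean_full = m, sd_full = s),
            class = "summary_row")
}

#' @export
print.summary_row <- function(x, ...) {
  cat(sprintf("%.2f (SD %.2f), n = %d\n", x$mean, x$sd, x$n))
  invisible(x)
}

#' Pool a postoperative 4-angle x 3-factor table
#'
#' The postoperative "all angles" summary pools all 12 values (4 flexion
#' angles x 3 correction factors) and then applies [pool()]; this pooling
#' rule reproduces the printed postoperative summary rows exactly.
#'
#' @param table 4 x 3 matrix or data frame (rows = angles 30/45/60/75,
#'   columns = factors 0.5/1.0/1.5).
#' @return a `summary_row`.
#' @export
pool_postop <- function(table) {
  tab <- as.matrix(table)
  if (!all(dim(tab) == c(4, 3))) {
    pf_stop("postoperative table must be 4 angles x 3 correction factors")
  }
  if (anyNA(tab)) {
    bad <- which(is.na(tab), arr.ind = TRUE)[1, ]
    pf_stop(sprintf("missing postoperative cell (theta row %d, factor column %d)",
                    bad[1], bad[2]))
  }
  pool(as.vector(tab))
}

#' Percent change
#'
#' `100 (after - before) / before`, rounded half-away-from-zero to integer
#' percent as printed.
#'
#' @param after,before values (MPa); `before > 0`.
#' @return integer percent.
#' @export
percent_change <- function(after, before) {
  if (any(before <= 0)) pf_stop("percent_change() requires before > 0")
  round_half_away(100 * (after - before) / before, 0)
}

#' Two-sample t-test (Student or Welch)
#'
#' @param a,b numeric samples (n >= 2 each).
#' @param welch use Welch's unequal-variance test with Satterthwaite degrees
#'   of freedom instead of the pooled-variance Student test.
#' @return list of class `comparison_result`: `t_statistic`,
#'   `degrees_of_freedom`, `p_value` (two-sided), `test`.
#' @export
t_test <- function(a, b, welch = FALSE) {
  if (length(a) < 2 || length(b) < 2) pf_stop("t_test() needs n >= 2 per group")
  t_test_summary(mean(a), stats::sd(a), length(a),
                 mean(b), stats::sd(b), length(b), welch = welch)
}

#' @describeIn t_test from summary statistics (for literature comparisons).
#' @param mean_a,sd_a,n_a,mean_b,sd_b,n_b group summary statistics.
#' @export
t_test_summary <- function(mean_a, sd_a, n_a, mean_b, sd_b, n_b,
                           welch = FALSE) {
  if (n_a < 2 || n_b < 2) pf_stop("t_test needs n >= 2 per group")
  va <- sd_a^2 / n_a; vb <- sd_b^2 / n_b
  if (va + vb == 0) {
    # zero variance in both groups: p = 1 for equal means (by convention),
    # else the difference is certain
    return(structure(list(t_statistic = if (mean_a == mean_b) 0 else Inf * sign(mean_a - mean_b),
                          degrees_of_freedom = n_a + n_b - 2,
                          p_value = if (mean_a == mean_b) 1 else 0,
                          test = if (welch) "welch" else "student"),
                     class = "comparison_result"))
  }
  if (welch) {
    se <- sqrt(va + vb)
    df <- (va + vb)^2 / (va^2 / (n_a - 1) + vb^2 / (n_b - 1))
  } else {
    sp2 <- ((n_a - 1) * sd_a^2 + (n_b - 1) * sd_b^2) / (n_a + n_b - 2)
    se <- sqrt(sp2 * (1 / n_a + 1 / n_b))
    df <- n_a + n_b - 2
  }
  tval <- (mean_a - mean_b) / se
  structure(list(t_statistic = tval, degrees_of_freedom = df,
                 p_value = 2 * stats::pt(-abs(tval), df),
                 test = if (welch) "welch" else "student"),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s t = %.3f, df = %.2f, p = %.3f\n", x$test, x$t_statistic,
              x$degrees_of_freedom, x$p_value))
  invisible(x)
}

#' Published patellofemoral reference tables
#'
#' Per-angle peak/mean contact pressures, equivalent stresses, alignment
#' indices, contact-area summaries and the experimental literature
#' comparison values from the published patellofemoral FE study of
#' trochleoplasty that this package's statistical workflow mirrors. These
#' printed values are inputs to the worked-example statistics (pooling,
#' percent change, t-tests); the package's own solver produces analogous
#' tables for the synthetic knees.
#'
#' @param which `"pressure"`, `"vmes"`, `"alignment"`, `"area"` or
#'   `"literature"`.
#' @return data frame.
#' @export
reference_table <- function(which = c("pressure", "vmes", "alignment",
                                      "area", "literature")) {
  which <- match.arg(which)
  f <- system.file("extdata", paste0("reference_", which, ".csv"),
                   package = "patellofem", mustWork = FALSE)
  if (!nzchar(f) || !file.exists(f)) {
    # source tree fallback (tests run before installation)
    f <- file.path("inst", "extdata", paste0("reference_", which, ".csv"))
  }
  utils::read.csv(f, check.names = FALSE)
}
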