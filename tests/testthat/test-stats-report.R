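# Statistical operators against the published per-angle tables: the pooled
# rows, percent changes and test statistics must reproduce the printed
# summary values from the printed per-angle values.

test_that("pooling reproduces the published contact-pressure summary rows", {
  tab <- reference_table("pressure")
  peak <- tab[tab$measure == "peak", ]
  mean_ <- tab[tab$measure == "mean", ]

  h <- pool(peak$healthy)
  expect_equal(h$mean, 1.97)
  expect_equal(h$sd, 0.16)

  pre <- pool(peak$preop)
  expect_equal(pre$mean, 2.43)
  expect_equal(pre$sd, 0.34)

  post <- pool_postop(peak[, c("f05", "f10", "f15")])
  expect_equal(post$mean, 3.30)
  expect_equal(post$sd, 1.01)
  expect_equal(post$n, 12L)

  expect_equal(pool(mean_$preop)$mean, 1.01)
  expect_equal(pool(mean_$preop)$sd, 0.13)
  post_m <- pool_postop(mean_[, c("f05", "f10", "f15")])
  expect_equal(post_m$mean, 1.23)
  expect_equal(post_m$sd, 0.17)
})

test_that("pooling reproduces the published equivalent-stress summary rows", {
  tab <- reference_table("vmes")
  pk_pat <- tab[tab$measure == "peak" & tab$region == "patella", ]
  pk_tro <- tab[tab$measure == "peak" & tab$region == "trochlea", ]
  expect_equal(pool(pk_pat$healthy)$mean, 0.87)
  expect_equal(pool(pk_pat$healthy)$sd, 0.12)
  expect_equal(pool_postop(pk_pat[, c("f05", "f10", "f15")])$mean, 1.35)
  expect_equal(pool_postop(pk_tro[, c("f05", "f10", "f15")])$mean, 1.50)
})

test_that("pool/pool_postop basics and error paths", {
  p <- pool(c(1, 1, 1, 1))
  expect_equal(p$mean, 1)
  expect_equal(p$sd, 0)
  expect_error(pool(c(1)), "at least two")
  expect_equal(pool_postop(matrix(2.5, 4, 3))$sd, 0)
  bad <- matrix(1, 4, 3); bad[2, 3] <- NA
  expect_error(pool_postop(bad), "missing postoperative cell")
  # flatten consistency: pool_postop == pool of the concatenated values
  set.seed(42)
  m <- matrix(runif(12, 1, 3), 4, 3)
  expect_identical(pool_postop(m)$mean_full, pool(as.vector(m))$mean_full)
})

test_that("percent change matches the printed table annotations", {
  expect_equal(percent_change(5.41, 2.61), 107)
  expect_equal(percent_change(3.75, 2.72), 38)
  expect_equal(percent_change(2, 2), 0)
  expect_error(percent_change(1, 0), "before > 0")
})

test_that("t-tests reproduce the printed comparisons", {
  tab <- reference_table("pressure")
  peak <- tab[tab$measure == "peak", ]
  st <- t_test(peak$healthy, peak$preop)
  expect_equal(st$degrees_of_freedom, 6)
  expect_close(abs(st$t_statistic), 2.48, 0.01)
  expect_close(st$p_value, 0.047, 0.002)   # prints as 0.047/0.048

  post <- unlist(peak[, c("f05", "f10", "f15")])
  w <- t_test(peak$preop, post, welch = TRUE)
  expect_close(w$p_value, 0.022, 0.001)    # printed 0.022 vs preoperative

  lit <- reference_table("literature")
  pk <- lit[lit$measure == "peak", ]
  ws <- t_test_summary(pk$model_mean, pk$model_sd, pk$n,
                       pk$lit_mean, pk$lit_sd, pk$n, welch = TRUE)
  expect_close(ws$t_statistic, 4.0, 0.1)
  expect_close(ws$degrees_of_freedom, 5.6, 0.1)
  expect_close(ws$p_value, 0.007, 0.002)   # printed 0.007
})

test_that("t-test properties: symmetry, summary equivalence, degeneracy", {
  set.seed(7)
  a <- rnorm(6, 1, 0.2); b <- rnorm(5, 1.3, 0.4)
  for (welch in c(FALSE, TRUE)) {
    r1 <- t_test(a, b, welch)
    r2 <- t_test(b, a, welch)
    expect_equal(r1$t_statistic, -r2$t_statistic)
    expect_equal(r1$p_value, r2$p_value)
    rs <- t_test_summary(mean(a), sd(a), length(a), mean(b), sd(b), length(b), welch)
    expect_equal(rs$t_statistic, r1$t_statistic, tolerance = 1e-12)
    expect_equal(rs$p_value, r1$p_value, tolerance = 1e-12)
    # cross-check against the stats package
    rt <- stats::t.test(a, b, var.equal = !welch)
    expect_equal(r1$t_statistic, unname(rt$statistic), tolerance = 1e-10)
    expect_equal(r1$p_value, rt$p.value, tolerance = 1e-10)
  }
  z <- t_test(c(1, 1), c(1, 1))
  expect_equal(z$t_statistic, 0)
  expect_equal(z$p_value, 1)
})

test_that("half-away-from-zero rounding matches the printed convention", {
  expect_equal(round_half_away(1.965, 2), 1.97)
  expect_equal(round_half_away(-1.965, 2), -1.97)
  expect_equal(round_half_away(0.5, 0), 1)
  expect_equal(round_half_away(2.43499, 2), 2.43)
})
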