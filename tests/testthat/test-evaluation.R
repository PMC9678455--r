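test_that("convergence rate is the converged fraction in percent", {
  rec <- make_records(estimate = rep(0.5, 1000), ci_low = 0.4, ci_high = 0.6,
                      truth = 0.5, converged = c(rep(TRUE, 974),
                                                 rep(FALSE, 26)))
  expect_equal(convergence_rate(rec), 97.4)
  expect_equal(convergence_rate(make_records(0.5, 0.4, 0.6, 0.5)), 100)
  rec$converged <- FALSE
  expect_equal(convergence_rate(rec), 0)
  expect_error(convergence_rate(rec[0, ]), "records")
})

test_that("coverage uses strict open intervals around the truth", {
  rec <- make_records(estimate = c(0.5, 0.65),
                      ci_low = c(0.4, 0.6), ci_high = c(0.6, 0.7),
                      truth = 0.5)
  expect_equal(ci_coverage(rec, "b1"), 50)
  # truth exactly on a bound is NOT covered
  edge <- make_records(estimate = 0.5, ci_low = 0.5, ci_high = 0.7,
                       truth = 0.5)
  expect_equal(ci_coverage(edge, "b1"), 0)
  edge2 <- make_records(estimate = 0.5, ci_low = 0.3, ci_high = 0.5,
                        truth = 0.5)
  expect_equal(ci_coverage(edge2, "b1"), 0)
  # non-converged replicates are excluded
  rec$converged <- c(TRUE, FALSE)
  expect_equal(ci_coverage(rec, "b1"), 100)
  rec$converged <- FALSE
  expect_true(is.na(ci_coverage(rec, "b1")))
})

test_that("coverage of exact normal intervals is nominal", {
  # oracle construction: truth +/- 1.96 SE intervals around normal draws
  set.seed(42)
  R <- 1e4; truth <- 0.5; se <- 0.1
  est <- rnorm(R, truth, se)
  rec <- make_records(est, est - 1.96 * se, est + 1.96 * se, truth)
  cover <- ci_coverage(rec, "b1")
  expect_lt(abs(cover - 95), 3 * 100 * sqrt(0.95 * 0.05 / R))
})

test_that("bias and rmse follow their definitions", {
  rec <- make_records(estimate = c(0.5, 0.5), ci_low = 0, ci_high = 1,
                      truth = 0.5)
  expect_equal(bias_metric(rec, "b1"), 0)
  expect_equal(rmse_metric(rec, "b1"), 0)

  two <- make_records(estimate = c(1.5, -0.5), ci_low = 0, ci_high = 1,
                      truth = 0.5)
  expect_equal(bias_metric(two, "b1"), 0)
  expect_equal(rmse_metric(two, "b1"), 1)

  three <- make_records(estimate = c(0.4, 0.6, 0.5), ci_low = 0, ci_high = 1,
                        truth = 0.5)
  expect_equal(bias_metric(three, "b1"), 0)
  expect_equal(rmse_metric(three, "b1"), sqrt(0.02 / 3))
})

test_that("rmse^2 - bias^2 equals the population variance of the errors", {
  set.seed(7)
  for (i in 1:5) {
    est <- rnorm(37, 0.5, 0.2)
    rec <- make_records(est, est - 1, est + 1, truth = 0.5)
    b <- bias_metric(rec, "b1"); r <- rmse_metric(rec, "b1")
    pop_var <- mean((est - 0.5 - mean(est - 0.5))^2)
    expect_equal(r^2 - b^2, pop_var, tolerance = 1e-12)
  }
})

test_that("metrics are invariant to record order", {
  set.seed(8)
  est <- rnorm(50, 0.5, 0.1)
  rec <- make_records(est, est - 0.2, est + 0.2, 0.5,
                      converged = runif(50) > 0.1)
  shuf <- rec[sample(nrow(rec)), ]
  for (f in list(convergence_rate,
                 function(x) ci_coverage(x, "b1"),
                 function(x) bias_metric(x, "b1"),
                 function(x) rmse_metric(x, "b1")))
    expect_equal(f(shuf), f(rec))
})

test_that("metric_table aggregates per condition and matches the scalars", {
  set.seed(9)
  est1 <- rnorm(40, 0.5, 0.1); est2 <- rnorm(40, 0.03, 0.02)
  rec <- rbind(
    make_records(est1, est1 - 0.15, est1 + 0.15, 0.5, parameter = "b1"),
    make_records(est2, est2 - 0.03, est2 + 0.03, 0.023,
                 parameter = "sigma2_U"))
  mt <- metric_table(rec)
  expect_equal(nrow(mt), 2)
  expect_equal(mt$coverage[mt$parameter == "b1"], ci_coverage(rec, "b1"))
  expect_equal(mt$bias[mt$parameter == "sigma2_U"],
               bias_metric(rec, "sigma2_U"))
  expect_equal(mt$rmse[mt$parameter == "sigma2_U"],
               rmse_metric(rec, "sigma2_U"))
  expect_true(all(mt$coverage >= 0 & mt$coverage <= 100))
  # display scaling only touches the formatted copy
  fm <- format_metric_table(mt, report_scale = 1e3)
  expect_equal(fm$bias, round(mt$bias * 1e3, 2))
  expect_equal(mt$bias, metric_table(rec)$bias)
})

test_that("grand summary reduces conditions with mean/median/min/max", {
  mt <- data.frame(
    c = c(8, 8, 12, 12), m = 5, rho = 0.05,
    prior_family = "gamma", parameter = "b1",
    convergence_rate = c(96, 98, 97, 99), coverage = c(90, 92, 94, 96),
    bias = c(-0.1, 0.1, 0.2, 0.4), rmse = c(0.1, 0.2, 0.3, 0.4),
    n_reps = 10, n_converged = 10)
  class(mt) <- c("metric_table", "data.frame")
  gs <- grand_summary(mt)
  cov <- gs[gs$metric == "coverage", ]
  expect_equal(cov$mean, 93)
  expect_equal(cov$median, 93)
  expect_equal(cov$min, 90)
  expect_equal(cov$max, 96)
  # one condition: all four statistics coincide
  g1 <- grand_summary(mt[1, ])
  expect_true(all(g1$mean == g1$median & g1$min == g1$max &
                  g1$mean == g1$min))
})

test_that("marginal summary averages over the chosen factor", {
  mt <- expand.grid(c = c(8, 12), m = c(5, 10), rho = 0.05,
                    prior_family = "uniform", parameter = "b1",
                    stringsAsFactors = FALSE)
  mt$convergence_rate <- 97
  mt$coverage <- c(90, 92, 94, 96)
  mt$bias <- 0.1; mt$rmse <- 0.2; mt$n_reps <- 5; mt$n_converged <- 5
  class(mt) <- c("metric_table", "data.frame")
  ms <- marginal_summary(mt, by = "c")
  cov <- ms[ms$metric == "coverage", ]
  expect_equal(cov$mean[cov$level == 8], mean(c(90, 94)))
  expect_equal(cov$mean[cov$level == 12], mean(c(92, 96)))
  # a factor the table is constant in gives identical rows
  msm <- marginal_summary(mt, by = "rho")
  expect_equal(nrow(msm[msm$metric == "coverage", ]), 1)
  expect_error(marginal_summary(mt, by = "bogus"))
})

test_that("metric tables round-trip through CSV", {
  est <- c(0.4, 0.5, 0.6)
  rec <- make_records(est, est - 0.2, est + 0.2, 0.5)
  mt <- metric_table(rec)
  path <- withr::local_tempfile(fileext = ".csv")
  write_metric_table(mt, path)
  back <- read_metric_table(path)
  expect_equal(back$rmse, mt$rmse)
  expect_s3_class(back, "metric_table")
})
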