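test_that("Gelman-Rubin diagnostic behaves at its reference points", {
  # identical constant chains
  expect_equal(gelman_rubin(matrix(5, 100, 3)), 1)
  # constant but different chains: zero within-chain variance, gross spread
  expect_identical(gelman_rubin(cbind(rep(1, 50), rep(2, 50))), Inf)
  # long i.i.d. chains from one distribution sit at 1
  set.seed(1)
  ch <- matrix(rnorm(3e4 * 3), ncol = 3)
  expect_lt(abs(gelman_rubin(ch) - 1), 0.01)
  # well-separated chains blow up
  set.seed(2)
  far <- cbind(rnorm(200, 0), rnorm(200, 10), rnorm(200, 20))
  expect_gt(gelman_rubin(far), 3)
  expect_error(gelman_rubin(matrix(1, 5, 2)), "10")
})

test_that("location block matches the closed-form GLS posterior", {
  # 30-subject dataset, variances clamped; long-run Gibbs mean/cov of
  # (b0, b1) against direct matrix inversion
  d <- generate_dataset(simulation_condition(5, 4, 0.15, n_control = 10),
                        seed = 99)
  s2U <- 0.069; s2eC <- 0.27; s2eU <- 0.391
  oracle <- gls_posterior(d, s2U, s2eC, s2eU)

  set.seed(1)
  state <- list(b0 = 0, b1 = 0, u = rep(0, 5),
                sigma2_U = s2U, sigma2_eC = s2eC, sigma2_eU = s2eU)
  n <- 30000
  draws <- matrix(NA_real_, n, 2)
  for (i in seq_len(n)) {
    state <- update_location_block(state, d)
    draws[i, ] <- c(state$b0, state$b1)
  }
  # mean within 3 MC standard errors (autocorrelation-adjusted via ESS)
  for (k in 1:2) {
    ess <- n / (2 * sum(acf(draws[, k], lag.max = 50,
                            plot = FALSE)$acf) - 1)
    mcse <- sd(draws[, k]) / sqrt(ess)
    expect_lt(abs(mean(draws[, k]) - oracle$mean[k]), 3 * mcse)
  }
  # covariance entries within 5%
  emp <- cov(draws)
  expect_lt(abs(emp[1, 1] - oracle$cov[1, 1]) / oracle$cov[1, 1], 0.05)
  expect_lt(abs(emp[2, 2] - oracle$cov[2, 2]) / oracle$cov[2, 2], 0.05)
  expect_lt(abs(emp[1, 2] - oracle$cov[1, 2]) / abs(oracle$cov[1, 2]), 0.05)
})

test_that("location block limits: shrinkage extremes of the cluster effects", {
  d <- generate_dataset(simulation_condition(6, 10, 0.1), seed = 4)
  tr <- d[d$arm == 1, ]
  cl_means <- as.numeric(tapply(tr$y, tr$cluster, mean))
  base <- list(b0 = 2, b1 = 0.5, u = rep(0, 6),
               sigma2_eC = 0.27, sigma2_eU = 0.414)

  # sigma2_U huge: no shrinkage, so u_j + b0 + b1 centers on the cluster mean
  set.seed(1)
  loose <- replicate(2000, {
    st <- base; st$sigma2_U <- 1e8
    out <- update_location_block(st, d)
    out$u + out$b0 + out$b1
  })
  se <- apply(loose, 1, sd) / sqrt(ncol(loose))
  expect_true(all(abs(rowMeans(loose) - cl_means) < 4 * se))

  # sigma2_U tiny: complete shrinkage to zero
  set.seed(1)
  tight <- replicate(200, {
    st <- base; st$sigma2_U <- 1e-10
    update_location_block(st, d)$u
  })
  expect_lt(max(abs(tight)), 1e-3)

  st <- base; st$sigma2_U <- -1
  expect_error(update_location_block(st, d), "positive")
})

test_that("truncated inverse-gamma draws match the analytic CDF", {
  set.seed(2)
  x <- rtrunc_invgamma(1e5, n = 12, S = 0.5, upper = 0.23)
  expect_true(all(x > 0 & x < 0.23))
  ks <- suppressWarnings(ks.test(x, trunc_invgamma_cdf(12, 0.5, 0.23)))
  expect_gt(ks$p.value, 0.01)

  # heavy truncation: most untruncated mass above the support
  x2 <- rtrunc_invgamma(1e5, n = 6, S = 3, upper = 0.23)
  expect_true(all(x2 > 0 & x2 < 0.23))
  ks2 <- suppressWarnings(ks.test(x2, trunc_invgamma_cdf(6, 3, 0.23)))
  expect_gt(ks2$p.value, 0.01)

  # all-zero residuals: conditional piles up at 0+, support respected
  x3 <- rtrunc_invgamma(100, n = 10, S = 0, upper = 0.23)
  expect_true(all(x3 < 0.23))
  expect_true(all(x3 < 1e-6))
})

test_that("gamma-prior M-H long-run density matches quadrature", {
  set.seed(3)
  pr <- variance_prior("gamma", shape = 13, scale = 0.03)
  res <- mh_gamma_variance(2.5e5, n = 20, S = 6, prior = pr, rw_step = 0.5,
                           init = 0.3)
  x <- res$sigma2[-(1:5000)]
  breaks <- seq(0.02, 1.5, length.out = 75)
  target <- gamma_variance_bin_probs(20, 6, pr, breaks)
  emp <- hist(x[x >= 0.02 & x < 1.5], breaks = breaks,
              plot = FALSE)$counts / length(x)
  tv <- 0.5 * sum(abs(emp - target))
  expect_lt(tv, 0.02)
  expect_gt(res$acceptance_rate, 0.2)
  expect_lt(res$acceptance_rate, 0.8)

  # degenerate proposal: a vanishing step accepts everything and moves nowhere
  res0 <- mh_gamma_variance(2000, n = 20, S = 6, prior = pr, rw_step = 1e-12,
                            init = 0.3)
  expect_gt(res0$acceptance_rate, 0.999)
  expect_lt(diff(range(res0$sigma2)), 1e-6)
})

test_that("fit_model is reproducible and keeps the draw bookkeeping", {
  d <- generate_dataset(simulation_condition(8, 5, 0.1), seed = 10)
  cs <- chain_settings(n_iter = 3000, n_burn = 1000, thin = 5, seed = 10)
  expect_equal(cs$retained_per_chain, 400L)
  expect_equal(chain_settings()$retained_per_chain, 4000L)

  f1 <- fit_model(d, canonical_regime("uniform"), cs)
  f2 <- fit_model(d, canonical_regime("uniform"), cs)
  expect_identical(f1$summary, f2$summary)
  expect_identical(f1$draws, f2$draws)
  expect_equal(nrow(f1$draws), 3 * 400)

  # interval bounds ordered; all uniform-regime draws inside the support
  expect_true(all(f1$summary$ci_low <= f1$summary$ci_high))
  expect_true(all(f1$draws[, "sigma2_U"] > 0 &
                  f1$draws[, "sigma2_U"] < 0.23))
  expect_true(all(f1$draws[, "sigma2_eC"] < 0.69))
  expect_true(all(f1$draws[, "sigma2_eU"] < 0.69))

  # a gamma-regime fit reports M-H acceptance rates
  fg <- fit_model(d, canonical_regime("gamma"), cs)
  expect_true(all(fg$acceptance_rates > 0 & fg$acceptance_rates < 1))

  # degenerate designs are rejected
  ctl_only <- d[d$arm == 0, ]
  expect_error(fit_model(ctl_only, canonical_regime("uniform"), cs),
               "control")
})

test_that("fits serialize to JSON and back", {
  d <- generate_dataset(simulation_condition(8, 5, 0.1), seed = 12)
  f <- fit_model(d, canonical_regime("gamma"),
                 chain_settings(n_iter = 2000, n_burn = 500, thin = 5,
                                seed = 12))
  path <- withr::local_tempfile(fileext = ".json")
  write_fit(f, path)
  back <- read_fit(path)
  expect_equal(back$summary$mean, f$summary$mean)
  expect_equal(back$converged, f$converged)
  expect_equal(back$settings$n_iter, 2000)
})
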