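# Shared oracle helpers. These are independent re-derivations (closed forms,
# direct matrix algebra, quadrature) of quantities the sampler computes by
# simulation; they must never call the sampler itself.

# Closed-form posterior of (b0, b1) for known variance components: marginal
# model y ~ N(Xb, V) with independent normal priors on b, via direct matrix
# inversion. V has sigma2_U added on each treatment cluster's block.
gls_posterior <- function(data, s2U, s2eC, s2eU, fixed = fixed_effect_priors()) {
  X <- cbind(1, data$arm)
  V <- diag(ifelse(data$arm == 0, s2eC, s2eU))
  for (j in unique(stats::na.omit(data$cluster))) {
    idx <- which(!is.na(data$cluster) & data$cluster == j)
    V[idx, idx] <- V[idx, idx] + s2U
  }
  S0inv <- diag(c(1 / fixed$b0_var, 1 / fixed$b1_var))
  m0 <- c(fixed$b0_mean, fixed$b1_mean)
  Vi <- solve(V)
  Sigma <- solve(t(X) %*% Vi %*% X + S0inv)
  list(mean = drop(Sigma %*% (t(X) %*% Vi %*% data$y + S0inv %*% m0)),
       cov = Sigma)
}

# Analytic CDF of the inverse-gamma(n/2 - 1, S/2) distribution truncated to
# (0, upper), via the gamma upper tail on the precision scale.
trunc_invgamma_cdf <- function(n, S, upper) {
  a <- n / 2 - 1
  b <- S / 2
  denom <- stats::pgamma(1 / upper, a, rate = b, lower.tail = FALSE)
  function(q) stats::pgamma(1 / q, a, rate = b, lower.tail = FALSE) / denom
}

# Quadrature-normalized density of the gamma-prior variance full conditional
# (n residuals, sum of squares S) on a fixed grid; returns bin probabilities
# for the given break points.
gamma_variance_bin_probs <- function(n, S, prior, breaks,
                                     grid_n = 4000L) {
  grid <- seq(min(breaks), max(breaks), length.out = grid_n)
  ld <- -(n / 2) * log(grid) - S / (2 * grid) + prior_log_density(prior, grid)
  dens <- exp(ld - max(ld))
  h <- diff(grid)[1]
  dens <- dens / sum(dens * h)
  probs <- vapply(seq_len(length(breaks) - 1L), function(i) {
    sum(dens[grid >= breaks[i] & grid < breaks[i + 1L]]) * h
  }, numeric(1))
  probs / sum(probs)
}

# Small deterministic replication-record frames for metric tests.
make_records <- function(estimate, ci_low, ci_high, truth, converged = TRUE,
                         parameter = "b1", c = 8L, m = 5L, rho = 0.05,
                         prior_family = "uniform") {
  n <- length(estimate)
  data.frame(c = c, m = m, rho = rho, prior_family = prior_family,
             rep = seq_len(n), parameter = parameter, converged = converged,
             estimate = estimate, ci_low = ci_low, ci_high = ci_high,
             truth = truth)
}
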