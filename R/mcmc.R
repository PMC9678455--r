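#' MCMC chain settings
#'
#' Defaults follow the reference protocol: 50,000 iterations with a 10,000
#' burn-in, thinning every 10th draw, three chains — 4,000 retained draws per
#' chain, 12,000 pooled.
#'
#' @param n_iter Total iterations per chain.
#' @param n_burn Burn-in iterations discarded (`< n_iter`).
#' @param thin Keep every `thin`-th post-burn-in draw.
#' @param n_chains Number of chains run from overdispersed starts.
#' @param rw_step Random-walk proposal SD on the log-variance scale for the
#'   gamma-prior Metropolis updates.
#' @param adapt Adapt `rw_step` during burn-in only (target 30-45%
#'   acceptance), frozen afterwards.
#' @param rhat_threshold Convergence declared when every monitored
#'   parameter's potential scale reduction factor is at or below this.
#' @param seed Integer seed; chain k uses `seed + k`.
#' @return A `chain_settings` list; `retained_per_chain` is derived.
#' @export
chain_settings <- function(n_iter = 50000L, n_burn = 10000L, thin = 10L,
                           n_chains = 3L, rw_step = 0.5, adapt = TRUE,
                           rhat_threshold = 1.1, seed = 1L) {
  n_iter <- as.integer(n_iter); n_burn <- as.integer(n_burn)
  thin <- as.integer(thin); n_chains <- as.integer(n_chains)
  stopifnot(n_burn >= 0L, n_burn < n_iter, thin >= 1L, n_chains >= 1L,
            rw_step > 0)
  structure(list(n_iter = n_iter, n_burn = n_burn, thin = thin,
                 n_chains = n_chains, rw_step = rw_step, adapt = adapt,
                 rhat_threshold = rhat_threshold, seed = as.integer(seed),
                 retained_per_chain = (n_iter - n_burn) %/% thin),
            class = "chain_settings")
}

# sufficient statistics of an ssind_data frame for the O(c)-per-iteration
# sampler: control count/sum/sum-of-squares plus per-cluster sums
suff_stats <- function(data) {
  ctl <- data$y[data$arm == 0L]
  tr <- data[data$arm == 1L, , drop = FALSE]
  if (length(ctl) == 0L || nrow(tr) == 0L)
    stop("model requires both a control arm and a treatment arm")
  sizes <- table(tr$cluster)
  m <- as.integer(sizes[[1L]])
  if (length(unique(as.integer(sizes))) != 1L)
    stop("unequal treatment cluster sizes are not supported")
  ord <- order(as.integer(names(sizes)))
  sumJ <- as.numeric(tapply(tr$y, tr$cluster, sum))[ord]
  sumsqJ <- as.numeric(tapply(tr$y^2, tr$cluster, sum))[ord]
  list(nC = length(ctl), sumC = sum(ctl), sumsqC = sum(ctl^2), m = m,
       c = length(sizes), sumJ = sumJ, sumsqJ = sumsqJ)
}

#' Gelman-Rubin potential scale reduction factor
#'
#' Computes `sqrt((W * (n - 1) / n + B / n) / W)` where `W` is the mean
#' within-chain variance and `B` the between-chain variance of the chain
#' means scaled by the chain length `n`.
#'
#' @param chains A numeric matrix (draws in rows, one column per chain) or a
#'   list of equal-length numeric vectors.
#' @return The PSRF (>= values near 1 indicate convergence). If every chain
#'   is the same constant sequence, returns 1; constant-but-different chains
#'   give `Inf`.
#' @export
gelman_rubin <- function(chains) {
  if (is.list(chains)) chains <- do.call(cbind, chains)
  chains <- as.matrix(chains)
  if (ncol(chains) < 2L) stop("need at least 2 chains")
  n <- nrow(chains)
  if (n < 10L) stop("need at least 10 retained draws per chain")
  W <- mean(apply(chains, 2L, stats::var))
  B <- n * stats::var(colMeans(chains))
  if (W == 0) return(if (B == 0) 1 else Inf)
  sqrt((W * (n - 1) / n + B / n) / W)
}

# effective sample size, per chain via the initial-positive-sequence rule on
# the empirical autocorrelations, summed over chains
effective_size <- function(chains) {
  ess_one <- function(x) {
    n <- length(x)
    if (stats::var(x) == 0) return(n)
    lag_max <- min(n - 1L, 200L)
    rho <- stats::acf(x, lag.max = lag_max, plot = FALSE,
                      demean = TRUE)$acf[-1L]
    s <- 0
    for (k in seq(1L, length(rho) - 1L, by = 2L)) {
      pair <- rho[k] + rho[k + 1L]
      if (is.na(pair) || pair <= 0) break
      s <- s + pair
    }
    n / (1 + 2 * s)
  }
  sum(apply(as.matrix(chains), 2L, ess_one))
}

#' One Gibbs sweep of the location block (b0, b1, u)
#'
#' Redraws the control mean, treatment effect and every cluster effect from
#' their exact normal full conditionals, holding the variance components
#' fixed. This is the identical routine the full sampler applies each
#' iteration; exposed for diagnostics and oracle testing.
#'
#' @param state List with elements `b0`, `b1`, `u` (length c), `sigma2_U`,
#'   `sigma2_eC`, `sigma2_eU` (all variances strictly positive).
#' @param data An `ssind_data` data frame.
#' @param regime A [prior_regime()] (only the fixed-effect priors are used).
#' @return The state with `b0`, `b1`, `u` replaced by fresh draws.
#' @export
update_location_block <- function(state, data, regime = canonical_regime("uniform")) {
  st <- suff_stats(data)
  if (any(c(state$sigma2_U, state$sigma2_eC, state$sigma2_eU) <= 0))
    stop("variances must be strictly positive")
  fx <- regime$fixed
  out <- location_step_cpp(st$nC, st$sumC, st$sumsqC, st$m, st$sumJ, st$sumsqJ,
                           state$sigma2_U, state$sigma2_eC, state$sigma2_eU,
                           fx$b0_mean, fx$b0_var, fx$b1_mean, fx$b1_var,
                           state$b0, state$b1, state$u)
  state$b0 <- out$b0; state$b1 <- out$b1; state$u <- out$u
  state
}

#' Draws from the truncated inverse-gamma variance full conditional
#'
#' Under a flat `U(0, upper)` prior, the full conditional of a variance with
#' `n` Gaussian residuals of sum-of-squares `S` is inverse-gamma with shape
#' `n/2 - 1` and rate `S/2`, truncated to `(0, upper)`. Drawn exactly by
#' inverse-CDF on the precision scale; the same routine the uniform-regime
#' sampler uses.
#'
#' @param n_draws Number of draws.
#' @param n Number of residuals contributing.
#' @param S Residual sum of squares.
#' @param upper Uniform prior upper bound.
#' @return Numeric vector of `n_draws` variances, all inside `(0, upper)`.
#' @export
rtrunc_invgamma <- function(n_draws, n, S, upper) {
  stopifnot(n_draws >= 1, upper > 0, S >= 0)
  rtrunc_invgamma_cpp(as.integer(n_draws), n, S, upper)
}

#' Random-walk Metropolis updates for a gamma-prior variance
#'
#' Runs `n_steps` Metropolis steps on `log(sigma2)` targeting the product of
#' the Gaussian likelihood (given `n` residuals with sum-of-squares `S`) and
#' a gamma(shape, scale) prior on the variance, including the log-transform
#' Jacobian. Identical kernel to the gamma-regime sampler's variance block.
#'
#' @param n_steps Number of Metropolis steps.
#' @param n,S Residual count and sum of squares.
#' @param prior A gamma-family [variance_prior()].
#' @param rw_step Proposal SD on the log scale.
#' @param init Initial variance (> 0).
#' @return List with `sigma2` (the chain) and `acceptance_rate`.
#' @export
mh_gamma_variance <- function(n_steps, n, S, prior, rw_step = 0.5,
                              init = prior$shape * prior$scale) {
  stopifnot(inherits(prior, "variance_prior"), prior$family == "gamma",
            init > 0)
  out <- mh_gamma_variance_chain_cpp(as.integer(n_steps), n, S, prior$shape,
                                     prior$scale, rw_step, init)
  list(sigma2 = out$sigma2, acceptance_rate = out$n_accepted / n_steps)
}

# overdispersed chain initialization; draws come from the priors (gamma
# variance draws clamped into (0.001, 1) to avoid absurd starting points)
init_chain_state <- function(regime, n_clusters) {
  fx <- regime$fixed
  draw_var <- function(prior) {
    if (prior$family == "uniform") stats::runif(1, 0, prior$upper)
    else min(max(stats::rgamma(1, shape = prior$shape, scale = prior$scale),
                 0.001), 1)
  }
  s2U <- draw_var(regime$prior_U)
  list(b0 = stats::rnorm(1, fx$b0_mean, sqrt(fx$b0_var)),
       b1 = stats::rnorm(1, fx$b1_mean, sqrt(fx$b1_var)),
       s2U = s2U, s2eC = draw_var(regime$prior_eC),
       s2eU = draw_var(regime$prior_eU),
       u = stats::rnorm(n_clusters, 0, sqrt(s2U)))
}

#' Fit the partially nested multilevel model by MCMC
#'
#' Runs `n_chains` Metropolis-within-Gibbs chains from overdispersed starts.
#' Each iteration redraws the location block (b0, b1, all u_j) from exact
#' normal full conditionals, then each variance component: an exact truncated
#' inverse-gamma draw under a uniform prior, or a random-walk Metropolis step
#' on the log variance under a gamma prior. Burn-in is discarded, retained
#' draws are thinned and pooled across chains for the posterior summaries.
#'
#' @param data An `ssind_data` data frame (see [generate_dataset()] or
#'   [read_dataset()]).
#' @param regime A [prior_regime()], e.g. [canonical_regime()].
#' @param settings A [chain_settings()] object; `settings$seed` makes the fit
#'   fully reproducible.
#' @return An object of class `ssind_fit`: list with `summary` (a data frame
#'   of posterior mean, sd, equal-tailed 95% interval bounds, split-free
#'   R-hat and effective sample size for b0, b1, sigma2_U, sigma2_eC,
#'   sigma2_eU), `converged` (all R-hat at or below the threshold),
#'   `acceptance_rates`, `fallbacks`, `settings`, and `draws` (pooled
#'   retained draws matrix).
#' @examples
#' d <- generate_dataset(simulation_condition(8, 5, 0.1), seed = 7)
#' fit <- fit_model(d, canonical_regime("uniform"),
#'                  chain_settings(n_iter = 2000, n_burn = 500, thin = 5,
#'                                 seed = 7))
#' fit$summary
#' @export
fit_model <- function(data, regime = canonical_regime("uniform"),
                      settings = chain_settings()) {
  stopifnot(inherits(regime, "prior_regime"),
            inherits(settings, "chain_settings"))
  st <- suff_stats(data)
  fx <- regime$fixed
  pU <- encode_prior(regime$prior_U)
  peC <- encode_prior(regime$prior_eC)
  peU <- encode_prior(regime$prior_eU)

  params <- c("b0", "b1", "sigma2_U", "sigma2_eC", "sigma2_eU")
  chains <- vector("list", settings$n_chains)
  acc <- matrix(NA_real_, settings$n_chains, 3,
                dimnames = list(NULL, c("sigma2_U", "sigma2_eC", "sigma2_eU")))
  fallbacks <- 0
  for (k in seq_len(settings$n_chains)) {
    set.seed(settings$seed + k)
    ini <- init_chain_state(regime, st$c)
    res <- run_chain_cpp(st$nC, st$sumC, st$sumsqC, st$m, st$sumJ, st$sumsqJ,
                         pU, peC, peU, fx$b0_mean, fx$b0_var, fx$b1_mean,
                         fx$b1_var, settings$n_iter, settings$n_burn,
                         settings$thin, settings$rw_step, settings$adapt,
                         c(ini$b0, ini$b1, ini$s2U, ini$s2eC, ini$s2eU),
                         ini$u, FALSE)
    chains[[k]] <- res$draws
    acc[k, ] <- res$acceptance
    fallbacks <- fallbacks + res$fallbacks
  }

  pooled <- do.call(rbind, chains)
  summ <- do.call(rbind, lapply(params, function(p) {
    per_chain <- sapply(chains, function(ch) ch[, p])
    x <- pooled[, p]
    q <- unname(stats::quantile(x, c(0.025, 0.975), type = 7))
    data.frame(parameter = p, mean = mean(x), sd = stats::sd(x),
               ci_low = q[1], ci_high = q[2],
               rhat = if (settings$n_chains >= 2L) gelman_rubin(per_chain)
                      else NA_real_,
               ess = effective_size(per_chain))
  }))
  rownames(summ) <- NULL
  rhats <- summ$rhat
  converged <- if (all(is.na(rhats))) NA
               else all(rhats <= settings$rhat_threshold)

  structure(list(summary = summ, converged = converged,
                 acceptance_rates = colMeans(acc), fallbacks = fallbacks,
                 settings = settings, regime_family = regime$family,
                 draws = pooled),
            class = "ssind_fit")
}

#' @export
print.ssind_fit <- function(x, ...) {
  cat("Partially nested multilevel model fit (", x$regime_family,
      " prior regime)\n", sep = "")
  cat("converged:", x$converged, "\n")
  print(x$summary, digits = 4)
  invisible(x)
}

#' Serialize a fit to JSON (and back)
#'
#' Draws are omitted; summaries, the convergence flag, acceptance rates and a
#' settings echo round-trip.
#'
#' @param fit An `ssind_fit`.
#' @param path File path for the JSON document.
#' @return `write_fit` returns `path` invisibly; `read_fit` returns the
#'   deserialized list.
#' @export
write_fit <- function(fit, path) {
  obj <- list(summary = fit$summary, converged = fit$converged,
              acceptance_rates = as.list(fit$acceptance_rates),
              fallbacks = fit$fallbacks,
              regime_family = fit$regime_family,
              settings = unclass(fit$settings))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       na = "null")
  invisible(path)
}

#' @rdname write_fit
#' @export
read_fit <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
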