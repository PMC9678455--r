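#' Deterministic sub-seed derivation
#'
#' A small multiplicative mixing chain (Lehmer steps modulo 2^31 - 1) mapping
#' `(master_seed, condition index, replicate index, stream)` to a positive
#' 31-bit seed. Pure: the same inputs always give the same sub-seed, so
#' replicates are independent of execution order and resumable.
#'
#' @param master_seed,cond_index,rep_index,stream Non-negative integers.
#' @return A positive integer below 2^31 - 1.
#' @export
sub_seed <- function(master_seed, cond_index, rep_index, stream = 0L) {
  mod <- 2147483647
  x <- (abs(as.numeric(master_seed)) %% mod)
  step <- function(x) (x * 48271) %% mod  # products stay below 2^53
  x <- step(x)
  x <- step((x + as.numeric(cond_index) * 69621 + 1) %% mod)
  x <- step((x + as.numeric(rep_index) * 30269 + 1) %% mod)
  x <- step((x + as.numeric(stream) * 10007 + 1) %% mod)
  as.integer(x %% (mod - 1) + 1)
}

#' Configuration of a Monte-Carlo study
#'
#' @param grid Data frame of conditions (columns `c`, `m`, `rho`,
#'   `n_control`; see [canonical_grid()]). Prior families are handled by
#'   `prior_families`, so duplicated grid rows differing only in
#'   `prior_family` are collapsed.
#' @param n_reps Replicates per condition (the reference protocol uses 1000).
#' @param chain_settings A [chain_settings()] object (its seed is overridden
#'   per replicate).
#' @param prior_families Families to fit; with both, each simulated dataset
#'   is analyzed under both regimes (common random numbers).
#' @param master_seed Master seed for the whole study.
#' @param truth Base [truth_parameters()]; its `rho` is replaced per
#'   condition.
#' @param output_dir Optional checkpoint directory: per-condition record CSVs
#'   are written there and finished conditions are skipped on re-runs.
#' @param swap_residual_priors Passed to [canonical_regime()] for the gamma
#'   family.
#' @return A `study_config` list.
#' @export
study_config <- function(grid = canonical_grid("gamma")[, c("c", "m", "rho",
                                                            "n_control")],
                         n_reps = 1000L,
                         chain_settings = ssindbayes::chain_settings(),
                         prior_families = c("gamma", "uniform"),
                         master_seed = 1L, truth = truth_parameters(),
                         output_dir = NULL, swap_residual_priors = FALSE) {
  stopifnot(is.data.frame(grid), all(c("c", "m", "rho") %in% names(grid)),
            n_reps >= 1L,
            all(prior_families %in% c("gamma", "uniform")))
  if (!"n_control" %in% names(grid)) grid$n_control <- grid$c * grid$m
  grid <- unique(grid[, c("c", "m", "rho", "n_control")])
  rownames(grid) <- NULL
  structure(list(grid = grid, n_reps = as.integer(n_reps),
                 chain_settings = chain_settings,
                 prior_families = unique(prior_families),
                 master_seed = as.integer(master_seed), truth = truth,
                 output_dir = output_dir,
                 swap_residual_priors = isTRUE(swap_residual_priors)),
            class = "study_config")
}

# fit one simulated dataset under one regime and flatten to record rows
replicate_records <- function(data, cond, rep_id, family, regime, settings,
                              truth) {
  fit <- tryCatch(fit_model(data, regime, settings), error = function(e) NULL)
  base <- data.frame(c = cond$c, m = cond$m, rho = cond$rho,
                     prior_family = family, rep = rep_id,
                     parameter = c("b1", "sigma2_U"), stringsAsFactors = FALSE)
  if (is.null(fit)) {  # failed fits count as non-converged, never abort
    base$converged <- FALSE
    base$estimate <- NA_real_; base$ci_low <- NA_real_
    base$ci_high <- NA_real_
  } else {
    s <- fit$summary
    idx <- match(c("b1", "sigma2_U"), s$parameter)
    base$converged <- isTRUE(fit$converged)
    base$estimate <- s$mean[idx]
    base$ci_low <- s$ci_low[idx]
    base$ci_high <- s$ci_high[idx]
  }
  base$truth <- c(truth$b1, truth$sigma2_U)
  base
}

#' Run a Monte-Carlo study over a condition grid
#'
#' For every condition and replicate: simulate one dataset, fit it under each
#' requested prior regime (the same dataset for both families — common random
#' numbers), and record the posterior point estimate and 95% interval of the
#' treatment effect `b1` and the nesting variance `sigma2_U` together with
#' the convergence verdict. Per-replicate fit failures are recorded as
#' non-converged. With `output_dir` set, per-condition record CSVs act as
#' checkpoints and are skipped when present.
#'
#' @param config A [study_config()].
#' @param progress Print one line per finished condition.
#' @return List with `records` (the replication-record data frame, see
#'   [evaluation-indices]) and `metrics` (its [metric_table()]).
#' @export
run_study <- function(config, progress = FALSE) {
  stopifnot(inherits(config, "study_config"))
  if (!is.null(config$output_dir) &&
      !dir.exists(config$output_dir) &&
      !dir.create(config$output_dir, recursive = TRUE, showWarnings = FALSE))
    stop("cannot create output directory ", config$output_dir)

  all_records <- vector("list", nrow(config$grid))
  for (ci in seq_len(nrow(config$grid))) {
    g <- config$grid[ci, ]
    ckpt <- if (!is.null(config$output_dir))
      file.path(config$output_dir,
                sprintf("records_c%d_m%d_rho%s.csv", g$c, g$m,
                        format(g$rho))) else NULL
    if (!is.null(ckpt) && file.exists(ckpt)) {
      all_records[[ci]] <- utils::read.csv(ckpt, stringsAsFactors = FALSE)
      next
    }
    cond <- simulation_condition(g$c, g$m, g$rho, n_control = g$n_control)
    truth <- truth_parameters(b0 = config$truth$b0, b1 = config$truth$b1,
                              sigma2_eC = config$truth$sigma2_eC,
                              total_treatment_var = config$truth$total_treatment_var,
                              rho = g$rho)
    regimes <- lapply(config$prior_families, function(f)
      canonical_regime(f, swap_residual_priors = config$swap_residual_priors &&
                            f == "gamma"))
    names(regimes) <- config$prior_families

    cond_rows <- vector("list", config$n_reps)
    for (r in seq_len(config$n_reps)) {
      data <- generate_dataset(cond, truth,
                               seed = sub_seed(config$master_seed, ci, r, 0L))
      rows <- lapply(seq_along(regimes), function(fi) {
        settings <- config$chain_settings
        settings$seed <- sub_seed(config$master_seed, ci, r, fi)
        replicate_records(data, cond, r, names(regimes)[fi], regimes[[fi]],
                          settings, truth)
      })
      cond_rows[[r]] <- do.call(rbind, rows)
    }
    rec <- do.call(rbind, cond_rows)
    if (!is.null(ckpt)) utils::write.csv(rec, ckpt, row.names = FALSE)
    if (progress)
      message(sprintf("condition %d/%d (c=%d, m=%d, rho=%.2f) done", ci,
                      nrow(config$grid), g$c, g$m, g$rho))
    all_records[[ci]] <- rec
  }
  records <- do.call(rbind, all_records)
  list(records = records, metrics = metric_table(records))
}

#' Recommend a prior family per condition
#'
#' Compares the two families' nesting-effect (`sigma2_U`) metrics within each
#' condition. Default rule: smaller RMSE wins; ties broken by coverage
#' closest to the nominal 95%, then by smaller absolute bias. Alternative
#' rules use coverage or bias as the primary criterion.
#'
#' @param table A [metric_table()] covering both prior families.
#' @param rule `"rmse"`, `"coverage"` or `"bias"` as the primary criterion.
#' @param parameter Parameter whose metrics drive the decision.
#' @return Data frame with `c`, `m`, `rho` and `recommended` (`"G"` gamma /
#'   `"U"` uniform).
#' @export
recommend_prior <- function(table, rule = c("rmse", "coverage", "bias"),
                            parameter = "sigma2_U") {
  rule <- match.arg(rule)
  t <- as.data.frame(table)
  t <- t[t$parameter == parameter, , drop = FALSE]
  key <- interaction(t$c, t$m, t$rho, drop = TRUE)
  rows <- lapply(split(t, key), function(g) {
    gam <- g[g$prior_family == "gamma", , drop = FALSE]
    uni <- g[g$prior_family == "uniform", , drop = FALSE]
    if (nrow(gam) != 1L || nrow(uni) != 1L)
      stop("both prior families required for every condition")
    crit <- function(row) {
      v <- c(rmse = row$rmse, coverage = abs(row$coverage - 95),
             bias = abs(row$bias))
      v[c(rule, setdiff(c("rmse", "coverage", "bias"), rule))]
    }
    cg <- crit(gam); cu <- crit(uni)
    pick <- "U"
    for (k in seq_along(cg)) {
      if (is.na(cg[k]) || is.na(cu[k])) next
      if (cg[k] < cu[k]) { pick <- "G"; break }
      if (cu[k] < cg[k]) { pick <- "U"; break }
    }
    data.frame(c = gam$c, m = gam$m, rho = gam$rho, recommended = pick)
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$rho, out$c, out$m), ]
  rownames(out) <- NULL
  out
}
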