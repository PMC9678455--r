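#' Evaluation indices for replicated simulation results
#'
#' Replication records are rows of a data frame with one row per (replicate,
#' parameter): columns `c`, `m`, `rho`, `prior_family`, `rep`, `converged`,
#' `parameter` (`"b1"` treatment effect or `"sigma2_U"` nesting effect),
#' `estimate`, `ci_low`, `ci_high`, `truth`. [run_study()] produces this
#' shape; hand-built frames work equally.
#'
#' * convergence rate: `100 * r / R`, `r` converged replicates out of `R`.
#' * coverage: percentage of converged replicates whose open interval
#'   `(ci_low, ci_high)` contains the truth (strict inequalities — a truth
#'   exactly on a bound is not covered).
#' * bias: mean of `estimate - truth` over converged replicates.
#' * rmse: root of the mean squared `estimate - truth` over converged
#'   replicates.
#'
#' @param records Replication-record data frame (one parameter's rows for
#'   `ci_coverage`, `bias_metric`, `rmse_metric`; any rows for
#'   `convergence_rate`, which counts unique replicates).
#' @param parameter Which parameter's records to use.
#' @return A scalar (percentage for rates/coverage, raw scale for
#'   bias/rmse); `NA` when no converged replicate is available.
#' @name evaluation-indices
NULL

filter_param <- function(records, parameter) {
  stopifnot(is.data.frame(records))
  r <- records[records$parameter == parameter, , drop = FALSE]
  if (nrow(r) == 0L) stop("no records for parameter ", parameter)
  r
}

#' @rdname evaluation-indices
#' @export
convergence_rate <- function(records) {
  stopifnot(is.data.frame(records))
  if (nrow(records) == 0L) stop("no replication records")
  per_rep <- tapply(records$converged, records$rep, function(z) all(z))
  100 * mean(per_rep)
}

#' @rdname evaluation-indices
#' @export
ci_coverage <- function(records, parameter = c("b1", "sigma2_U")) {
  parameter <- match.arg(parameter)
  r <- filter_param(records, parameter)
  r <- r[r$converged, , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  100 * mean(r$ci_low < r$truth & r$truth < r$ci_high)
}

#' @rdname evaluation-indices
#' @export
bias_metric <- function(records, parameter = c("b1", "sigma2_U")) {
  parameter <- match.arg(parameter)
  r <- filter_param(records, parameter)
  r <- r[r$converged, , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  mean(r$estimate - r$truth)
}

#' @rdname evaluation-indices
#' @export
rmse_metric <- function(records, parameter = c("b1", "sigma2_U")) {
  parameter <- match.arg(parameter)
  r <- filter_param(records, parameter)
  r <- r[r$converged, , drop = FALSE]
  if (nrow(r) == 0L) return(NA_real_)
  sqrt(mean((r$estimate - r$truth)^2))
}

#' Aggregate replication records into a per-condition metric table
#'
#' One row per (condition, prior family, parameter) carrying the four
#' indices plus replicate counts. Bias and RMSE are stored on the raw
#' parameter scale; `report_scale` multiplies them only in
#' [format_metric_table()].
#'
#' @param records Replication-record data frame (see
#'   [evaluation-indices]).
#' @return A `metric_table` data frame with columns `c`, `m`, `rho`,
#'   `prior_family`, `parameter`, `convergence_rate`, `coverage`, `bias`,
#'   `rmse`, `n_reps`, `n_converged`.
#' @export
metric_table <- function(records) {
  stopifnot(is.data.frame(records), nrow(records) > 0L)
  key <- interaction(records$c, records$m, records$rho, records$prior_family,
                     records$parameter, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    conv <- g[g$converged, , drop = FALSE]
    data.frame(
      c = g$c[1L], m = g$m[1L], rho = g$rho[1L],
      prior_family = g$prior_family[1L], parameter = g$parameter[1L],
      convergence_rate = 100 * mean(g$converged),
      coverage = if (nrow(conv)) 100 * mean(conv$ci_low < conv$truth &
                                            conv$truth < conv$ci_high)
                 else NA_real_,
      bias = if (nrow(conv)) mean(conv$estimate - conv$truth) else NA_real_,
      rmse = if (nrow(conv)) sqrt(mean((conv$estimate - conv$truth)^2))
             else NA_real_,
      n_reps = nrow(g), n_converged = nrow(conv))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$prior_family, out$rho, out$c, out$m, out$parameter), ]
  rownames(out) <- NULL
  class(out) <- c("metric_table", "data.frame")
  out
}

metric_cols <- c("convergence_rate", "coverage", "bias", "rmse")

#' Grand summary across conditions
#'
#' For each prior family, parameter and metric: the mean, median, minimum and
#' maximum over the condition-level values (not over pooled replicates — the
#' printed extrema remain attributable to single conditions).
#'
#' @param table A [metric_table()].
#' @return Long data frame with columns `prior_family`, `parameter`,
#'   `metric`, `mean`, `median`, `min`, `max`, `n_conditions`.
#' @export
grand_summary <- function(table) {
  stopifnot(is.data.frame(table), nrow(table) > 0L)
  key <- interaction(table$prior_family, table$parameter, drop = TRUE)
  rows <- lapply(split(as.data.frame(table), key), function(g) {
    do.call(rbind, lapply(metric_cols, function(mc) {
      v <- g[[mc]]
      data.frame(prior_family = g$prior_family[1L],
                 parameter = g$parameter[1L], metric = mc,
                 mean = mean(v, na.rm = TRUE),
                 median = stats::median(v, na.rm = TRUE),
                 min = min(v, na.rm = TRUE), max = max(v, na.rm = TRUE),
                 n_conditions = sum(!is.na(v)))
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Marginal summary along one grid factor
#'
#' Means of each metric over all conditions sharing a level of `by`, per
#' prior family and parameter — the numbers behind factor-wise comparison
#' panels.
#'
#' @param table A [metric_table()].
#' @param by `"c"`, `"m"` or `"rho"`.
#' @return Long data frame with columns `by`, `level`, `prior_family`,
#'   `parameter`, `metric`, `mean`, `n_conditions`.
#' @export
marginal_summary <- function(table, by = c("c", "m", "rho")) {
  by <- match.arg(by)
  if (!by %in% names(table)) stop("factor ", by, " absent from table")
  key <- interaction(table[[by]], table$prior_family, table$parameter,
                     drop = TRUE)
  rows <- lapply(split(as.data.frame(table), key), function(g) {
    do.call(rbind, lapply(metric_cols, function(mc) {
      data.frame(by = by, level = g[[by]][1L],
                 prior_family = g$prior_family[1L],
                 parameter = g$parameter[1L], metric = mc,
                 mean = mean(g[[mc]], na.rm = TRUE),
                 n_conditions = sum(!is.na(g[[mc]])))
    }))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$prior_family, out$parameter, out$metric, out$level), ]
  rownames(out) <- NULL
  out
}

#' Format a metric table for display
#'
#' Applies a multiplier to the bias and RMSE columns (they are stored on the
#' raw parameter scale) and rounds.
#'
#' @param table A [metric_table()].
#' @param report_scale Multiplier for bias and RMSE (e.g. `1e3`).
#' @param digits Rounding digits.
#' @return A plain data frame.
#' @export
format_metric_table <- function(table, report_scale = 1, digits = 2) {
  out <- as.data.frame(table)
  out$bias <- round(out$bias * report_scale, digits)
  out$rmse <- round(out$rmse * report_scale, digits)
  out$convergence_rate <- round(out$convergence_rate, digits)
  out$coverage <- round(out$coverage, digits)
  out
}

#' Write / read a metric table as tidy CSV
#'
#' @param table A [metric_table()].
#' @param path File path.
#' @return `write_metric_table` returns `path` invisibly;
#'   `read_metric_table` returns a `metric_table`.
#' @export
write_metric_table <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metric_table
#' @export
read_metric_table <- function(path) {
  out <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(out) <- c("metric_table", "data.frame")
  out
}
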