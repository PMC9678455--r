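#' Truth parameters of the partially nested generative model
#'
#' The generative model is
#' \deqn{Y_{ij} = b_0 + b_1 X_{ij} + u_j Z_j + e_{ij},}
#' where \eqn{X_{ij}} indicates treatment, \eqn{u_j \sim N(0, \sigma^2_U)} is
#' the cluster (nesting) effect present only in the treatment arm, control
#' residuals are \eqn{N(0, \sigma^2_{eC})} and treatment residuals
#' \eqn{N(0, \sigma^2_{eU})}. The total treatment-arm variance is split by the
#' intraclass correlation \eqn{\rho}: \eqn{\sigma^2_U = \rho \cdot
#' \mathrm{total}}, \eqn{\sigma^2_{eU} = (1-\rho) \cdot \mathrm{total}}.
#'
#' Defaults correspond to the canonical study conditions: control mean 2,
#' treatment effect 0.5, control residual variance 0.27, total treatment-arm
#' variance 0.46.
#'
#' @param b0 Control-condition mean.
#' @param b1 Treatment effect (treatment minus control mean difference).
#' @param sigma2_eC Control-arm residual variance (>= 0).
#' @param total_treatment_var Total variance under treatment (>= 0).
#' @param rho Intraclass correlation under treatment, in \[0, 1).
#' @return An object of class `truth_parameters`: a list with the five inputs
#'   plus the derived components `sigma2_U` and `sigma2_eU`.
#' @examples
#' truth_parameters(rho = 0.05)
#' @export
truth_parameters <- function(b0 = 2, b1 = 0.5, sigma2_eC = 0.27,
                             total_treatment_var = 0.46, rho = 0.1) {
  stopifnot(is.numeric(b0), is.numeric(b1), length(rho) == 1L)
  if (sigma2_eC < 0) stop("sigma2_eC must be non-negative")
  vc <- derive_variance_components(rho, total_treatment_var)
  structure(
    list(b0 = b0, b1 = b1, sigma2_eC = sigma2_eC,
         total_treatment_var = total_treatment_var, rho = rho,
         sigma2_U = vc[["sigma2_U"]], sigma2_eU = vc[["sigma2_eU"]]),
    class = "truth_parameters"
  )
}

#' Split a total variance into nesting and individual components
#'
#' @param rho Intraclass correlation in \[0, 1).
#' @param total_var Total variance (>= 0).
#' @return Named numeric vector `c(sigma2_U, sigma2_eU)` with
#'   `sigma2_U = rho * total_var` and `sigma2_eU = (1 - rho) * total_var`;
#'   the two sum to `total_var` exactly.
#' @examples
#' derive_variance_components(0.05, 0.46)  # 0.023, 0.437
#' @export
derive_variance_components <- function(rho, total_var) {
  if (!is.numeric(rho) || length(rho) != 1L || is.na(rho) ||
      rho < 0 || rho >= 1)
    stop("rho must lie in [0, 1)")
  if (!is.numeric(total_var) || length(total_var) != 1L || is.na(total_var) ||
      total_var < 0)
    stop("total_var must be non-negative")
  s2U <- rho * total_var
  c(sigma2_U = s2U, sigma2_eU = total_var - s2U)
}

#' One cell of the simulation condition grid
#'
#' @param c Number of treatment clusters (>= 2).
#' @param m Subjects per treatment cluster (>= 2).
#' @param rho Intraclass correlation under treatment.
#' @param prior_family `"gamma"` or `"uniform"`.
#' @param n_control Control-arm size; defaults to `c * m` (balanced arms).
#' @return A `simulation_condition` list.
#' @export
simulation_condition <- function(c, m, rho, prior_family = c("uniform", "gamma"),
                                 n_control = c * m) {
  prior_family <- match.arg(prior_family)
  c <- as.integer(c); m <- as.integer(m); n_control <- as.integer(n_control)
  stopifnot(c >= 2L, m >= 2L, n_control >= 2L, rho >= 0, rho < 1)
  structure(list(c = c, m = m, rho = rho, prior_family = prior_family,
                 n_control = n_control),
            class = "simulation_condition")
}

#' The canonical 72-condition grid
#'
#' Fully crosses c in {8, 12, 16}, m in {5, 10, 15, 20}, rho in
#' {0.05, 0.10, 0.15} and the two prior families (36 cells per family).
#'
#' @param prior_families Character vector of families to include.
#' @return A data frame with one row per condition and columns
#'   `c`, `m`, `rho`, `prior_family`, `n_control`.
#' @export
canonical_grid <- function(prior_families = c("gamma", "uniform")) {
  g <- expand.grid(m = c(5L, 10L, 15L, 20L), c = c(8L, 12L, 16L),
                   rho = c(0.05, 0.10, 0.15),
                   prior_family = prior_families,
                   KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  g <- g[order(g$prior_family, g$rho, g$c, g$m), c("c", "m", "rho",
                                                   "prior_family")]
  g$n_control <- g$c * g$m
  rownames(g) <- NULL
  g
}

#' Generate one partially nested two-arm dataset
#'
#' Control outcomes are i.i.d. `N(b0, sigma2_eC)`. The outcome of subject i in
#' treatment cluster j is `b0 + b1 + u_j + e_ij` with `u_j ~ N(0, sigma2_U)`
#' and `e_ij ~ N(0, sigma2_eU)`. Control subjects carry `NA` in the `cluster`
#' column: they belong to no cluster, so no random effect can attach to them.
#'
#' @param condition A [simulation_condition()] (its `rho` overrides the
#'   truth's when they differ).
#' @param truth A [truth_parameters()] object.
#' @param seed Integer seed; the same seed reproduces the dataset exactly.
#' @return A data frame of class `ssind_data` with columns `subject_id`,
#'   `arm` (0 control / 1 treatment), `cluster` (1..c or `NA`), `y`, and
#'   attributes `true_group_effects` (the realized `u_j`), `truth`,
#'   `condition`.
#' @examples
#' d <- generate_dataset(simulation_condition(8, 5, 0.05), seed = 1)
#' table(d$arm)
#' @export
generate_dataset <- function(condition, truth = truth_parameters(rho = condition$rho),
                             seed) {
  stopifnot(inherits(condition, "simulation_condition"))
  if (!inherits(truth, "truth_parameters")) stop("truth must be truth_parameters")
  if (!isTRUE(all.equal(truth$rho, condition$rho)))
    truth <- truth_parameters(b0 = truth$b0, b1 = truth$b1,
                              sigma2_eC = truth$sigma2_eC,
                              total_treatment_var = truth$total_treatment_var,
                              rho = condition$rho)
  set.seed(as.integer(seed))
  nC <- condition$n_control; cc <- condition$c; m <- condition$m

  y_control <- stats::rnorm(nC, truth$b0, sqrt(truth$sigma2_eC))
  u <- stats::rnorm(cc, 0, sqrt(truth$sigma2_U))
  e <- stats::rnorm(cc * m, 0, sqrt(truth$sigma2_eU))
  cluster_t <- rep(seq_len(cc), each = m)
  y_treat <- truth$b0 + truth$b1 + u[cluster_t] + e

  out <- data.frame(
    subject_id = seq_len(nC + cc * m),
    arm = c(rep(0L, nC), rep(1L, cc * m)),
    cluster = c(rep(NA_integer_, nC), cluster_t),
    y = c(y_control, y_treat)
  )
  attr(out, "true_group_effects") <- u
  attr(out, "truth") <- truth
  attr(out, "condition") <- condition
  class(out) <- c("ssind_data", "data.frame")
  out
}

#' One-way ANOVA moment estimator of the treatment-arm ICC
#'
#' Computes `(MSB - MSW) / (MSB + (m - 1) * MSW)` from the between/within
#' decomposition of the treatment arm. Used in generator self-checks; can be
#' negative when cluster means vary less than chance predicts.
#'
#' @param dataset An `ssind_data` data frame (needs >= 2 equal-size clusters
#'   of >= 2 subjects).
#' @return The estimated ICC (scalar).
#' @export
empirical_icc <- function(dataset) {
  tr <- dataset[dataset$arm == 1L, , drop = FALSE]
  sizes <- table(tr$cluster)
  if (length(sizes) < 2L) stop("need at least 2 treatment clusters")
  if (length(unique(as.integer(sizes))) != 1L)
    stop("clusters must be of equal size")
  m <- as.integer(sizes[[1L]])
  if (m < 2L) stop("cluster size must be >= 2")
  cc <- length(sizes)
  means <- tapply(tr$y, tr$cluster, mean)
  msb <- m * sum((means - mean(tr$y))^2) / (cc - 1)
  msw <- sum((tr$y - means[as.character(tr$cluster)])^2) / (cc * (m - 1))
  (msb - msw) / (msb + (m - 1) * msw)
}

#' Write / read a partially nested dataset as headered CSV
#'
#' Columns: `subject_id`, `arm`, `cluster` (empty for control subjects), `y`.
#' Attributes (`true_group_effects`, `truth`, `condition`) are not persisted.
#'
#' @param dataset An `ssind_data` data frame.
#' @param path File path.
#' @return `write_dataset` returns `path` invisibly; `read_dataset` returns an
#'   `ssind_data` data frame.
#' @export
write_dataset <- function(dataset, path) {
  utils::write.csv(as.data.frame(dataset)[, c("subject_id", "arm", "cluster",
                                              "y")],
                   path, row.names = FALSE, na = "")
  invisible(path)
}

#' @rdname write_dataset
#' @export
read_dataset <- function(path) {
  d <- utils::read.csv(path, colClasses = c(subject_id = "integer",
                                            arm = "integer",
                                            cluster = "integer",
                                            y = "numeric"))
  if (!all(c("subject_id", "arm", "cluster", "y") %in% names(d)))
    stop("not a partially nested dataset CSV")
  if (any(d$arm == 1L & is.na(d$cluster)))
    stop("treatment subjects must carry a cluster label")
  if (any(d$arm == 0L & !is.na(d$cluster)))
    stop("control subjects must not carry a cluster label")
  class(d) <- c("ssind_data", "data.frame")
  d
}
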