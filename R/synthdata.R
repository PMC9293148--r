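#' Configure a synthetic presence-absence simulation
#'
#' Describes a presence-absence dataset with the statistical structure the
#' habitat analysis assumes: a known sparse set of driver covariates
#' generating presence probability through a logistic link, controlled
#' correlation among continuous covariates, manufactured near-duplicate
#' columns (to exercise collinearity screening), and severe class imbalance
#' (presences far fewer than absences, as in satellite-survey seal data).
#'
#' @param n_presence number of presence records to generate (>= 1).
#' @param n_absence number of absence records to generate (>= 1).
#' @param covariate_names character vector of covariate identifiers.
#' @param correlation symmetric positive semi-definite matrix in `[-1, 1]`
#'   with unit diagonal, one row/column per covariate. Default: identity.
#' @param driver_coefficients named numeric vector of logistic-scale
#'   coefficients; names must be declared covariates. Covariates not named
#'   get coefficient 0. Default: all zero (a null model).
#' @param intercept logistic-scale intercept (controls baseline prevalence).
#' @param collinear_pairs list of `list(source=, copy=, noise_sd=)` entries;
#'   each appends a column `copy = source + N(0, noise_sd)`, a manufactured
#'   near-duplicate whose variance inflation factor exceeds any reasonable
#'   threshold when `noise_sd` is small.
#' @param exp_transform character vector of covariate names to report on the
#'   exponential scale, giving the positive right-skewed distributions of
#'   distance-to-feature covariates. Drivers act on the transformed column
#'   as stored; the transform is monotone, so ordering-based learners see
#'   the same signal.
#' @param seed integer root seed.
#' @return an object of class `sim_config`.
#' @seealso [simulate_dataset()], [generate_covariates()]
#' @export
sim_config <- function(n_presence,
                       n_absence,
                       covariate_names,
                       correlation = NULL,
                       driver_coefficients = NULL,
                       intercept = 0,
                       collinear_pairs = list(),
                       exp_transform = character(),
                       seed = 1L) {
  stopifnot(n_presence >= 1, n_absence >= 1)
  p <- length(covariate_names)
  if (p < 1) stop("at least one covariate name required")
  if (anyDuplicated(covariate_names)) stop("covariate names must be unique")

  if (is.null(correlation)) correlation <- diag(p)
  correlation <- as.matrix(correlation)
  if (!all(dim(correlation) == c(p, p)))
    stop("correlation must be ", p, "x", p)
  if (max(abs(correlation - t(correlation))) > 1e-12)
    stop("correlation matrix must be symmetric")
  if (max(abs(diag(correlation) - 1)) > 1e-12)
    stop("correlation matrix must have unit diagonal")
  ev <- eigen(correlation, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) < -1e-8)
    stop("correlation matrix is not positive semi-definite ",
         "(smallest eigenvalue ", signif(min(ev), 3), ")")

  beta <- stats::setNames(numeric(p), covariate_names)
  if (!is.null(driver_coefficients)) {
    if (is.null(names(driver_coefficients)) || any(names(driver_coefficients) == ""))
      stop("driver_coefficients must be a named vector")
    bad <- setdiff(names(driver_coefficients), covariate_names)
    if (length(bad))
      stop("driver_coefficients refer to undeclared covariates: ",
           paste(bad, collapse = ", "))
    beta[names(driver_coefficients)] <- driver_coefficients
  }

  all_names <- covariate_names
  for (cp in collinear_pairs) {
    if (!all(c("source", "copy") %in% names(cp)))
      stop("each collinear pair needs 'source' and 'copy'")
    if (!cp$source %in% covariate_names)
      stop("collinear pair source '", cp$source, "' is not a declared covariate")
    if (cp$copy %in% all_names)
      stop("collinear pair copy '", cp$copy, "' clashes with an existing name")
    all_names <- c(all_names, cp$copy)
  }
  bad <- setdiff(exp_transform, all_names)
  if (length(bad)) stop("exp_transform names not declared: ",
                        paste(bad, collapse = ", "))

  structure(
    list(n_presence = as.integer(n_presence),
         n_absence = as.integer(n_absence),
         covariate_names = covariate_names,
         correlation = correlation,
         driver_coefficients = beta,
         intercept = intercept,
         collinear_pairs = collinear_pairs,
         exp_transform = exp_transform,
         seed = as.integer(seed)),
    class = "sim_config")
}

#' Draw the covariate matrix for a simulation
#'
#' Rows are drawn from a multivariate normal with the configured correlation
#' structure; manufactured collinear copies are appended afterwards, and any
#' `exp_transform` columns are exponentiated. Deterministic given the
#' config seed.
#'
#' @param config a [sim_config()].
#' @param n number of rows; defaults to `n_presence + n_absence`.
#' @return numeric matrix (rows x covariates) with column names.
#' @export
generate_covariates <- function(config, n = NULL) {
  stopifnot(inherits(config, "sim_config"))
  n <- as.integer(n %||% (config$n_presence + config$n_absence))
  set.seed(child_seed(config$seed, "covariates"))
  p <- length(config$covariate_names)
  X <- MASS::mvrnorm(n, mu = rep(0, p), Sigma = config$correlation)
  X <- matrix(X, nrow = n, dimnames = list(NULL, config$covariate_names))
  for (cp in config$collinear_pairs) {
    noise_sd <- cp$noise_sd %||% 0
    copy <- X[, cp$source] + if (noise_sd > 0) stats::rnorm(n, 0, noise_sd) else 0
    X <- cbind(X, copy)
    colnames(X)[ncol(X)] <- cp$copy
  }
  for (v in config$exp_transform) X[, v] <- exp(X[, v])
  X
}

#' Generate an occurrence table with exact class counts
#'
#' Presence labels are Bernoulli draws with probability
#' `plogis(intercept + X %*% driver_coefficients)`. Candidate rows are
#' resampled (with replacement) and relabelled until exactly `n_presence`
#' presences and `n_absence` absences have been accumulated, so the output
#' class totals match the configuration exactly for any seed — mirroring
#' survey datasets whose class counts are fixed observed quantities.
#'
#' @param covariates matrix from [generate_covariates()].
#' @param config the same [sim_config()].
#' @return an object of class `synthetic_dataset`: a list with `table`
#'   (the occurrence data frame), `truth` (generating intercept,
#'   coefficients and driver set) and `config`.
#' @export
generate_occurrence <- function(covariates, config) {
  stopifnot(inherits(config, "sim_config"), is.matrix(covariates))
  beta <- config$driver_coefficients
  # coefficients act on declared covariates only; copies carry no direct effect
  eta <- config$intercept + covariates[, names(beta), drop = FALSE] %*% beta
  prob <- stats::plogis(drop(eta))
  if (all(prob < 1e-3) || all(prob > 1 - 1e-3))
    warning("presence probability is degenerate (all ~0 or all ~1); ",
            "labels will be dominated by forced relabelling")

  set.seed(child_seed(config$seed, "occurrence"))
  need_p <- config$n_presence
  need_a <- config$n_absence
  pres_rows <- integer(0)
  abs_rows <- integer(0)
  n <- nrow(covariates)
  tries <- 0L
  while ((length(pres_rows) < need_p || length(abs_rows) < need_a) && tries < 200L) {
    tries <- tries + 1L
    batch <- sample.int(n, size = max(1000L, 2L * (need_p + need_a)), replace = TRUE)
    lab <- stats::runif(length(batch)) < prob[batch]
    if (length(pres_rows) < need_p) pres_rows <- c(pres_rows, batch[lab])
    if (length(abs_rows) < need_a) abs_rows <- c(abs_rows, batch[!lab])
  }
  # degenerate probabilities: fill the starved class by forced relabelling
  if (length(pres_rows) < need_p)
    pres_rows <- c(pres_rows, sample.int(n, need_p - length(pres_rows), replace = TRUE))
  if (length(abs_rows) < need_a)
    abs_rows <- c(abs_rows, sample.int(n, need_a - length(abs_rows), replace = TRUE))
  pres_rows <- pres_rows[seq_len(need_p)]
  abs_rows <- abs_rows[seq_len(need_a)]

  rows <- c(pres_rows, abs_rows)
  presence <- rep(c(1L, 0L), c(need_p, need_a))
  ord <- sample.int(length(rows))  # shuffle so class blocks are interleaved
  table <- data.frame(
    id = sprintf("r%06d", seq_along(rows)),
    presence = presence[ord],
    covariates[rows[ord], , drop = FALSE],
    row.names = NULL, check.names = FALSE)
  validate_occurrence(table)

  drivers <- names(beta)[beta != 0]
  structure(
    list(table = table,
         truth = list(intercept = config$intercept,
                      coefficients = beta,
                      drivers = drivers),
         config = config),
    class = "synthetic_dataset")
}

#' One-call synthetic dataset
#'
#' @inheritParams generate_occurrence
#' @param config a [sim_config()].
#' @return a `synthetic_dataset` (see [generate_occurrence()]).
#' @export
simulate_dataset <- function(config) {
  generate_occurrence(generate_covariates(config), config)
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat("Synthetic presence-absence dataset\n")
  cat("  records:  ", nrow(x$table),
      " (", sum(x$table$presence == 1), " presence / ",
      sum(x$table$presence == 0), " absence)\n", sep = "")
  cat("  covariates:", ncol(x$table) - 2L, "\n")
  cat("  true drivers:",
      if (length(x$truth$drivers)) paste(x$truth$drivers, collapse = ", ")
      else "(none - null model)", "\n")
  invisible(x)
}

#' Generate an expert climate-change score sheet
#'
#' Raters independently score each environmental variable from 0 (no
#' expected change under climate change) to 3 (high expected change).
#' Designated variables can be forced to a constant score, mirroring the
#' anchor cases of the elicitation: distance-to-ice-edge-type variables
#' pinned at 3, bathymetry-type variables pinned at 0.
#'
#' @param variables character vector of variable names.
#' @param n_raters number of raters (>= 1).
#' @param seed integer seed.
#' @param forced named numeric vector: variables whose score every rater is
#'   forced to give (values in 0..3).
#' @return data frame, rows = raters, columns = variables, entries in 0..3.
#' @export
generate_score_sheet <- function(variables, n_raters, seed = 1L, forced = NULL) {
  stopifnot(n_raters >= 1, length(variables) >= 1)
  if (!is.null(forced)) {
    bad <- setdiff(names(forced), variables)
    if (length(bad)) stop("forced scores for unknown variables: ",
                          paste(bad, collapse = ", "))
    if (!all(forced %in% 0:3)) stop("forced scores must be integers in 0..3")
  }
  set.seed(child_seed(seed, "scores"))
  sheet <- matrix(sample(0:3, n_raters * length(variables), replace = TRUE),
                  nrow = n_raters,
                  dimnames = list(paste0("rater", seq_len(n_raters)), variables))
  for (v in names(forced)) sheet[, v] <- forced[[v]]
  as.data.frame(sheet)
}
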