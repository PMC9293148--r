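#' Variance inflation factors for the covariates of an occurrence table
#'
#' For each covariate j, `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is the
#' coefficient of determination of an ordinary least-squares regression of
#' covariate j on all the other covariates. Perfect linear dependence is
#' reported as unbounded (`Inf` with `unbounded = TRUE`), not as a float
#' overflow.
#'
#' @param table occurrence table (see [validate_occurrence()]), or a plain
#'   data frame / matrix of covariates.
#' @return data frame with columns `variable`, `vif`, `unbounded`.
#' @export
compute_vif <- function(table) {
  X <- if (is.data.frame(table) && all(c("id", "presence") %in% names(table)))
    covariate_matrix(table) else as.matrix(table)
  p <- ncol(X)
  if (p < 2) stop("VIF needs at least 2 covariates")
  if (nrow(X) < p + 1) stop("VIF needs at least covariates + 1 records")
  sds <- apply(X, 2, stats::sd)
  if (any(sds == 0))
    stop("constant covariate column(s): ",
         paste(colnames(X)[sds == 0], collapse = ", "))
  vif <- vapply(seq_len(p), function(j) {
    fit <- stats::lm.fit(cbind(1, X[, -j, drop = FALSE]), X[, j])
    r2 <- 1 - sum(fit$residuals^2) / sum((X[, j] - mean(X[, j]))^2)
    if (r2 > 1 - 1e-10) Inf else 1 / (1 - r2)
  }, numeric(1))
  data.frame(variable = colnames(X), vif = vif,
             unbounded = is.infinite(vif), row.names = NULL)
}

#' Iterative collinearity screening by VIF
#'
#' Repeatedly removes the single covariate with the largest VIF (ties broken
#' alphabetically), recomputing after each removal, until every remaining
#' covariate has VIF at or below the threshold. The default threshold of 10
#' is the conventional cut for strong collinearity. Stepwise removal is used
#' rather than one-shot exclusion of everything above the threshold, because
#' under shared collinearity one-shot removal discards variables that become
#' acceptable once their partners are gone; each removal is logged so the
#' alternative is recoverable.
#'
#' @param table occurrence table.
#' @param threshold maximum acceptable VIF (default 10).
#' @return object of class `vif_report`: list with `vif` (final per-variable
#'   table), `retained` (character), `removed` (data frame: variable,
#'   vif_at_removal, step), `threshold`.
#' @export
filter_by_vif <- function(table, threshold = 10) {
  has_meta <- is.data.frame(table) && all(c("id", "presence") %in% names(table))
  X <- if (has_meta) covariate_matrix(table) else as.matrix(table)
  removed <- data.frame(variable = character(), vif_at_removal = numeric(),
                        step = integer())
  step <- 0L
  repeat {
    if (ncol(X) < 2) {
      warning("fewer than 2 covariates remain; stopping VIF filtering")
      vif_tab <- data.frame(variable = colnames(X),
                            vif = rep(NA_real_, ncol(X)),
                            unbounded = FALSE)
      break
    }
    vif_tab <- compute_vif(X)
    if (max(vif_tab$vif) <= threshold) break
    step <- step + 1L
    worst <- vif_tab[vif_tab$vif == max(vif_tab$vif), "variable"]
    worst <- sort(worst)[1]  # deterministic alphabetical tie-break
    removed <- rbind(removed, data.frame(
      variable = worst,
      vif_at_removal = vif_tab$vif[vif_tab$variable == worst],
      step = step))
    X <- X[, setdiff(colnames(X), worst), drop = FALSE]
  }
  structure(list(vif = vif_tab, retained = colnames(X),
                 removed = removed, threshold = threshold),
            class = "vif_report")
}

#' @export
print.vif_report <- function(x, ...) {
  cat("VIF screening (threshold ", x$threshold, ")\n", sep = "")
  cat("  retained: ", length(x$retained), " variable(s)\n", sep = "")
  if (nrow(x$removed)) {
    cat("  removed (in order):\n")
    for (i in seq_len(nrow(x$removed)))
      cat(sprintf("    %d. %s (VIF %.4g)\n", x$removed$step[i],
                  x$removed$variable[i], x$removed$vif_at_removal[i]))
  } else cat("  removed: none\n")
  invisible(x)
}

#' Balanced hold-out split
#'
#' Holds out `floor(presence_fraction * total presences)` presence records,
#' selected uniformly at random, plus an equal number of absence records,
#' also uniform over records — so the test set has equal presence and
#' absence counts while the training remainder keeps its class imbalance.
#' An explicit presence count can override the fraction.
#'
#' @param table occurrence table.
#' @param presence_fraction fraction of presence records to hold out
#'   (default 0.2); interpreted relative to presences, not all records.
#' @param seed integer seed.
#' @param n_test_presence explicit number of hold-out presences, overriding
#'   the fraction.
#' @return object of class `data_split`: list with `train`, `test`, `seed`.
#' @export
make_holdout <- function(table, presence_fraction = 0.2, seed = 1L,
                         n_test_presence = NULL) {
  validate_occurrence(table)
  stopifnot(presence_fraction >= 0, presence_fraction < 1)
  pres_idx <- which(table$presence == 1)
  abs_idx <- which(table$presence == 0)
  n_tp <- if (!is.null(n_test_presence)) as.integer(n_test_presence)
          else floor(presence_fraction * length(pres_idx))
  if (n_tp > length(pres_idx))
    stop("requested ", n_tp, " hold-out presences but only ",
         length(pres_idx), " available")
  if (n_tp > length(abs_idx))
    stop("requested balance of ", n_tp, " absences exceeds the ",
         length(abs_idx), " available")
  set.seed(child_seed(seed, "holdout"))
  test_p <- sample(pres_idx, n_tp)
  test_a <- sample(abs_idx, n_tp)
  test_rows <- sort(c(test_p, test_a))
  test <- table[test_rows, , drop = FALSE]
  train <- table[setdiff(seq_len(nrow(table)), test_rows), , drop = FALSE]
  rownames(test) <- rownames(train) <- NULL
  structure(list(train = train, test = test, seed = as.integer(seed)),
            class = "data_split")
}

#' @export
print.data_split <- function(x, ...) {
  cat("Balanced hold-out split\n")
  cat("  train:", nrow(x$train), "records (",
      sum(x$train$presence == 1), "presence )\n")
  cat("  test: ", nrow(x$test), "records (",
      sum(x$test$presence == 1), "presence /",
      sum(x$test$presence == 0), "absence )\n")
  invisible(x)
}

#' Draw one balanced bootstrap sample
#'
#' Each bootstrap contains every training presence record exactly once plus
#' a random sample of absence records of equal size, so the class ratio is
#' exactly 1:1 and the sample size is twice the presence count. Absences are
#' sampled without replacement when the pool is large enough, otherwise with
#' replacement.
#'
#' @param train training occurrence table (from [make_holdout()]).
#' @param bootstrap_id integer identifier of the replicate.
#' @param seed integer root seed; combined with `bootstrap_id` so each
#'   replicate has its own reproducible stream.
#' @return object of class `bootstrap_sample`: list with `bootstrap_id`,
#'   `records` (occurrence table).
#' @export
draw_bootstrap <- function(train, bootstrap_id, seed = 1L) {
  validate_occurrence(train)
  pres_idx <- which(train$presence == 1)
  abs_idx <- which(train$presence == 0)
  if (!length(pres_idx) || !length(abs_idx))
    stop("bootstrap needs at least one presence and one absence")
  set.seed(child_seed(seed, "bootstrap", bootstrap_id))
  k <- length(pres_idx)
  sampled_abs <- if (length(abs_idx) >= k) sample(abs_idx, k)
                 else sample(abs_idx, k, replace = TRUE)
  records <- train[c(pres_idx, sampled_abs), , drop = FALSE]
  rownames(records) <- NULL
  structure(list(bootstrap_id = as.integer(bootstrap_id), records = records),
            class = "bootstrap_sample")
}
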