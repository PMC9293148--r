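#' Specify an ensemble member learner and its tuning grid
#'
#' The ensemble has three member families: a random forest (`"rf"`, backed
#' by ranger), boosted regression trees (`"brt"`, backed by xgboost) and the
#' in-package maximum-entropy presence/background learner (`"maxent"`, see
#' [fit_maxent()]). Each member is tuned per bootstrap by grid search with
#' k-fold cross-validation, selecting the candidate with the highest pooled
#' out-of-fold R-squared against the 0/1 labels.
#'
#' @param learner_type one of `"rf"`, `"brt"`, `"maxent"`.
#' @param grid data frame of candidate hyperparameter rows, or `NULL` to use
#'   [default_grid()] (resolved against the data at fit time). Columns:
#'   rf — `mtry`, `num_trees`; brt — `eta`, `max_depth`, `nrounds`;
#'   maxent — `reg_mult` (and optionally `classes`, a comma-separated
#'   feature-class string).
#' @param cv_folds number of cross-validation folds (default 10, >= 2).
#' @param metric `"r_squared"` (1 - SS_res/SS_tot of pooled out-of-fold
#'   predictions vs labels; the default) or `"cor_squared"` (squared Pearson
#'   correlation).
#' @return object of class `learner_spec`.
#' @export
learner_spec <- function(learner_type = c("rf", "brt", "maxent"),
                         grid = NULL, cv_folds = 10L,
                         metric = c("r_squared", "cor_squared")) {
  learner_type <- match.arg(learner_type)
  metric <- match.arg(metric)
  if (cv_folds < 2) stop("cv_folds must be >= 2")
  if (!is.null(grid)) {
    grid <- as.data.frame(grid)
    if (nrow(grid) < 1) stop("tuning grid must be non-empty")
  }
  structure(list(learner_type = learner_type, grid = grid,
                 cv_folds = as.integer(cv_folds), metric = metric),
            class = "learner_spec")
}

#' Default tuning grids
#'
#' Conventional grids for ecological presence-absence SDMs: random forest
#' tries per-split candidate counts of ceiling(sqrt(p)), ceiling(p/3) and p
#' with 500 trees; boosted trees cross learning rates 0.01/0.1, interaction
#' depths 1/3 and 100/500 trees; maxent tries regularisation multipliers
#' 0.5, 1 and 2.
#'
#' @param learner_type one of `"rf"`, `"brt"`, `"maxent"`.
#' @param p number of covariates (needed for rf).
#' @return data frame of candidates.
#' @export
default_grid <- function(learner_type, p = NULL) {
  switch(learner_type,
    rf = {
      if (is.null(p)) stop("rf default grid needs the covariate count p")
      data.frame(mtry = unique(c(ceiling(sqrt(p)), ceiling(p / 3), p)),
                 num_trees = 500L)
    },
    brt = expand.grid(eta = c(0.01, 0.1), max_depth = c(1L, 3L),
                      nrounds = c(100L, 500L)),
    maxent = data.frame(reg_mult = c(0.5, 1, 2)),
    stop("unknown learner type: ", learner_type))
}

# Random fold assignment: a partition of 1..n into k folds whose sizes
# differ by at most one record.
make_folds <- function(n, k, seed) {
  set.seed(seed)
  sample(rep_len(seq_len(k), n))
}

# Fit one candidate on (X, y). Returns an object predict_member() accepts.
fit_learner <- function(learner_type, X, y, hyper, seed) {
  switch(learner_type,
    rf = ranger::ranger(
      x = as.data.frame(X), y = factor(y, levels = c(0, 1)),
      probability = TRUE,
      num.trees = hyper$num_trees %||% 500L,
      mtry = min(hyper$mtry %||% ceiling(sqrt(ncol(X))), ncol(X)),
      seed = seed, num.threads = 1L),
    brt = {
      nrounds <- hyper$nrounds %||% 100L
      if (nrounds == 0L) {
        # intercept-only degenerate candidate: constant base score
        structure(list(base_score = 0.5), class = "constant_model")
      } else {
        set.seed(seed)
        dtrain <- xgboost::xgb.DMatrix(as.matrix(X), label = y)
        xgboost::xgb.train(
          params = list(objective = "binary:logistic",
                        eta = hyper$eta %||% 0.1,
                        max_depth = hyper$max_depth %||% 3L,
                        nthread = 1L),
          data = dtrain, nrounds = nrounds, verbose = 0)
      }
    },
    maxent = {
      classes <- if (!is.null(hyper$classes))
        strsplit(hyper$classes, ",", fixed = TRUE)[[1]]
      else c("linear", "quadratic")
      # normalise over the whole balanced sample (presences are part of the
      # available environment); an absence-only background can leave the
      # presence feature means outside the background hull, making the
      # maximum-entropy objective unbounded
      fit_maxent(X[y == 1, , drop = FALSE], X,
                 expansion = maxent_features(classes = classes),
                 regularization = hyper$reg_mult %||% 1)
    },
    stop("unknown learner type: ", learner_type))
}

predict_model <- function(learner_type, model, X) {
  X <- as.matrix(X)
  if (inherits(model, "constant_model")) return(rep(model$base_score, nrow(X)))
  switch(learner_type,
    rf = {
      pr <- stats::predict(model, data = as.data.frame(X),
                           num.threads = 1L)$predictions
      pr[, "1"]
    },
    brt = stats::predict(model, newdata = xgboost::xgb.DMatrix(X)),
    maxent = predict(model, X))
}

# Simplicity ordering used for CV ties: fewer trees / larger regularisation
# first, then declaration order.
simplicity_order <- function(learner_type, grid) {
  key <- switch(learner_type,
    rf = order(grid$num_trees %||% rep(0, nrow(grid)),
               seq_len(nrow(grid))),
    brt = order(grid$nrounds %||% rep(0, nrow(grid)),
                grid$max_depth %||% rep(0, nrow(grid)),
                seq_len(nrow(grid))),
    maxent = order(-(grid$reg_mult %||% rep(0, nrow(grid))),
                   seq_len(nrow(grid))))
  key
}

#' Tune and fit one ensemble member on a balanced bootstrap sample
#'
#' Records are randomly partitioned into `cv_folds` folds of approximately
#' equal size (sizes differ by at most 1). For each grid candidate the
#' out-of-fold predictions are pooled and scored against the 0/1 labels;
#' the candidate maximising the CV score is refit on the full sample.
#' Ties are broken by the simpler candidate (fewer trees / larger
#' regularisation), then declaration order.
#'
#' @param sample a [draw_bootstrap()] sample (balanced, retained covariates
#'   only).
#' @param spec a [learner_spec()].
#' @param seed integer seed driving fold assignment and any stochastic
#'   fitting.
#' @return object of class `fitted_member`: learner type, bootstrap id,
#'   chosen hyperparameters, CV score, the fitted model and its covariate
#'   names.
#' @export
tune_and_fit <- function(sample, spec, seed = 1L) {
  stopifnot(inherits(sample, "bootstrap_sample"), inherits(spec, "learner_spec"))
  data <- sample$records
  y <- data$presence
  if (length(unique(y)) < 2) stop("degenerate sample: a single class")
  X <- covariate_matrix(data)
  n <- nrow(X)
  grid <- spec$grid %||% default_grid(spec$learner_type, p = ncol(X))

  folds <- make_folds(n, spec$cv_folds,
                      seed = child_seed(seed, "folds", sample$bootstrap_id))

  cv_scores <- vapply(seq_len(nrow(grid)), function(ci) {
    hyper <- as.list(grid[ci, , drop = FALSE])
    preds <- numeric(n)
    for (f in seq_len(spec$cv_folds)) {
      in_fold <- folds == f
      if (!any(in_fold)) next
      ytr <- y[!in_fold]
      if (length(unique(ytr)) < 2) {
        preds[in_fold] <- mean(ytr)
        next
      }
      m <- fit_learner(spec$learner_type, X[!in_fold, , drop = FALSE], ytr,
                       hyper, seed = child_seed(seed, "cvfit", ci * 1000L + f))
      preds[in_fold] <- predict_model(spec$learner_type, m,
                                      X[in_fold, , drop = FALSE])
    }
    if (spec$metric == "r_squared") r_squared(y, preds)
    else r_squared(y, preds, type = "cor_squared")
  }, numeric(1))

  best <- which(cv_scores >= max(cv_scores) - 1e-12)
  if (length(best) > 1) {
    ord <- simplicity_order(spec$learner_type, grid)
    best <- ord[ord %in% best][1]
  }
  hyper <- as.list(grid[best, , drop = FALSE])
  model <- fit_learner(spec$learner_type, X, y, hyper,
                       seed = child_seed(seed, "finalfit", sample$bootstrap_id))
  structure(
    list(learner_type = spec$learner_type,
         bootstrap_id = sample$bootstrap_id,
         hyperparameters = hyper,
         cv_score = cv_scores[best],
         cv_scores = stats::setNames(cv_scores, seq_len(nrow(grid))),
         model = model,
         variables = colnames(X),
         n_records = n),
    class = "fitted_member")
}

#' Predict probability of presence from a fitted ensemble member
#'
#' @param object a `fitted_member` from [tune_and_fit()].
#' @param newdata occurrence table, data frame or matrix containing every
#'   covariate the member was trained on; unknown/missing covariates are
#'   rejected.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.fitted_member <- function(object, newdata, ...) {
  X <- if (is.data.frame(newdata) && all(c("id", "presence") %in% names(newdata)))
    covariate_matrix(newdata) else as.matrix(newdata)
  miss <- setdiff(object$variables, colnames(X))
  if (length(miss))
    stop("newdata is missing covariate(s): ", paste(miss, collapse = ", "))
  X <- X[, object$variables, drop = FALSE]
  p <- predict_model(object$learner_type, object$model, X)
  pmin(pmax(p, 0), 1)
}

#' @export
print.fitted_member <- function(x, ...) {
  cat("Fitted ", toupper(x$learner_type), " member (bootstrap ",
      x$bootstrap_id, ")\n", sep = "")
  cat("  hyperparameters:",
      paste(names(x$hyperparameters), unlist(x$hyperparameters),
            sep = "=", collapse = ", "), "\n")
  cat("  CV score:", signif(x$cv_score, 4), "\n")
  invisible(x)
}
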