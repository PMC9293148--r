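#' Permutation variable importance for an ensemble member
#'
#' For each covariate, the evaluation metric (default AUC) is recomputed
#' after shuffling that covariate's column, and the importance is the
#' baseline metric minus the mean metric over `n_permutations` independent
#' shuffles. By default the member is evaluated on its own bootstrap
#' records (in-bag), matching common packaged behaviour; any occurrence
#' table can be supplied instead.
#'
#' @param member a [tune_and_fit()] member.
#' @param data occurrence table to evaluate on (must contain both classes).
#' @param metric `"auc"` (default) or `"r_squared"`.
#' @param n_permutations independent shuffles per covariate (default 5);
#'   0 is the degenerate identity path and returns all-zero importances.
#' @param seed integer seed.
#' @return named numeric vector of raw importances (may be negative).
#' @export
permutation_importance <- function(member, data, metric = c("auc", "r_squared"),
                                   n_permutations = 5L, seed = 1L) {
  stopifnot(inherits(member, "fitted_member"))
  metric <- match.arg(metric)
  validate_occurrence(data)
  y <- data$presence
  if (metric == "auc" && length(unique(y)) < 2)
    stop("metric undefined: data has a single class")
  X <- covariate_matrix(data)[, member$variables, drop = FALSE]
  score <- function(Xe) {
    p <- predict_model(member$learner_type, member$model, Xe)
    if (metric == "auc") auc(y, p) else r_squared(y, p)
  }
  baseline <- score(X)
  if (n_permutations == 0L)
    return(stats::setNames(numeric(ncol(X)), colnames(X)))
  set.seed(child_seed(seed, "perm", member$bootstrap_id))
  imp <- vapply(colnames(X), function(v) {
    perm_scores <- vapply(seq_len(n_permutations), function(i) {
      Xp <- X
      Xp[, v] <- X[sample.int(nrow(X)), v]
      score(Xp)
    }, numeric(1))
    baseline - mean(perm_scores)
  }, numeric(1))
  imp
}

#' Relative influence (percentage contribution) of a boosted-trees member
#'
#' For a BRT member the importance of a covariate is its share of the total
#' split gain (squared-error/loss reduction summed over every split on that
#' covariate across all trees), normalised to percentages summing to 100.
#' The per-split gain records are read from the member's own tree dump.
#'
#' @param member a BRT [tune_and_fit()] member.
#' @return named numeric vector of percentages over the member's covariates
#'   (variables never split on get 0).
#' @export
brt_relative_influence <- function(member) {
  stopifnot(inherits(member, "fitted_member"))
  if (member$learner_type != "brt")
    stop("relative influence is defined for BRT members only")
  if (inherits(member$model, "constant_model"))
    stop("member has no gain records (intercept-only model)")
  dump <- as.data.frame(xgboost::xgb.model.dt.tree(model = member$model))
  gain_col <- intersect(c("Gain", "Quality"), names(dump))[1]
  splits <- dump[dump$Feature != "Leaf", , drop = FALSE]
  gains <- stats::setNames(numeric(length(member$variables)), member$variables)
  if (nrow(splits)) {
    agg <- tapply(splits[[gain_col]], splits$Feature, sum)
    gains[names(agg)] <- agg
  }
  total <- sum(gains)
  if (total <= 0) stop("member has no positive split gain")
  100 * gains / total
}

#' Normalise raw importances to proportions
#'
#' Negative raw importances (possible under permutation) are clipped to 0,
#' then each is divided by the sum, so per member the proportional
#' importances form a point on the simplex — the normalisation that makes
#' permutation importance and percentage contribution comparable across
#' model families.
#'
#' @param raw named numeric vector of raw importances.
#' @return named numeric vector summing to 1.
#' @export
proportional_importance <- function(raw) {
  clipped <- pmax(raw, 0)
  s <- sum(clipped)
  if (s <= 0)
    stop("all raw importances are zero after clipping; proportions undefined")
  clipped / s
}

#' Raw + proportional importance records for one member
#'
#' Dispatches on the member family: permutation importance for RF and
#' maxent members, split-gain relative influence for BRT members; then
#' normalises to proportions. Members whose raw importances are all zero
#' after clipping (pure-noise fits) yield `NULL` with a warning so callers
#' can count and exclude them.
#'
#' @param member a [tune_and_fit()] member.
#' @param data occurrence table for permutation importance (default: not
#'   needed for BRT).
#' @param n_permutations,seed passed to [permutation_importance()].
#' @return data frame `learner_type, bootstrap_id, variable, raw,
#'   proportional`, or `NULL` for a zero-information member.
#' @export
member_importance <- function(member, data = NULL, n_permutations = 5L,
                              seed = 1L) {
  raw <- if (member$learner_type == "brt") {
    tryCatch(brt_relative_influence(member), error = function(e) NULL)
  } else {
    if (is.null(data)) stop("permutation importance needs evaluation data")
    permutation_importance(member, data, n_permutations = n_permutations,
                           seed = seed)
  }
  if (is.null(raw)) {
    warning("member carries no importance signal; excluded")
    return(NULL)
  }
  prop <- tryCatch(proportional_importance(raw), error = function(e) NULL)
  if (is.null(prop)) {
    warning("member importances all zero after clipping; excluded")
    return(NULL)
  }
  data.frame(learner_type = member$learner_type,
             bootstrap_id = member$bootstrap_id,
             variable = names(raw),
             raw = unname(raw),
             proportional = unname(prop),
             row.names = NULL)
}

#' Aggregate proportional importance across bootstraps
#'
#' Groups importance records by (learner type, variable) and reports the
#' mean and standard deviation of proportional importance across bootstrap
#' replicates — the quantities plotted per model family in the importance
#' figures.
#'
#' @param records long data frame from [member_importance()] rows bound
#'   together.
#' @return data frame `learner_type, variable, mean_proportional,
#'   sd_proportional, n_bootstraps`, sorted by learner type then descending
#'   mean.
#' @export
aggregate_importance <- function(records) {
  stopifnot(all(c("learner_type", "variable", "proportional") %in% names(records)))
  key <- interaction(records$learner_type, records$variable, drop = TRUE)
  agg <- do.call(rbind, lapply(split(records, key), function(g) {
    data.frame(learner_type = g$learner_type[1],
               variable = g$variable[1],
               mean_proportional = mean(g$proportional),
               sd_proportional = if (nrow(g) > 1) stats::sd(g$proportional) else 0,
               n_bootstraps = nrow(g))
  }))
  agg <- agg[order(agg$learner_type, -agg$mean_proportional, agg$variable), ]
  rownames(agg) <- NULL
  agg
}
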