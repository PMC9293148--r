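#' Average expert ratings into climate change scores
#'
#' Each rater scores each environmental variable from 0 (no expected change
#' under climate change) to 3 (high expected change); the per-variable
#' arithmetic mean across raters is the variable's climate change score.
#'
#' @param sheet data frame or matrix, rows = raters, columns = variables,
#'   integer entries in 0..3 with every variable scored by every rater.
#' @return named numeric vector of climate change scores in `[0, 3]`.
#' @export
average_scores <- function(sheet) {
  m <- as.matrix(sheet)
  if (!is.numeric(m)) stop("score sheet must be numeric")
  if (anyNA(m)) stop("every variable must be scored by every rater")
  if (!all(m %in% 0:3))
    stop("scores must be integers in 0..3; offending values: ",
         paste(unique(m[!m %in% 0:3]), collapse = ", "))
  colMeans(m)
}

#' Change importance product
#'
#' The headline climate-sensitivity index: for each (variable, model
#' family) pair, the climate change score multiplied by the mean
#' proportional importance, giving a value in `[0, 3]` that is large only
#' for variables that are both influential in the habitat models and
#' expected to change substantially. An unweighted mean across the model
#' families gives each variable a single overall value, on which variables
#' are ranked in descending order.
#'
#' @param importance_agg output of [aggregate_importance()].
#' @param scores named climate change scores from [average_scores()]; a
#'   score must exist for every variable with importance.
#' @return data frame of class `cip_table`: `variable, learner_type,
#'   climate_change_score, mean_proportional_importance, product,
#'   overall_mean_product, rank` (dense descending rank on the overall
#'   mean), sorted by rank then learner type.
#' @export
change_importance_product <- function(importance_agg, scores) {
  stopifnot(all(c("learner_type", "variable", "mean_proportional") %in%
                  names(importance_agg)))
  missing <- setdiff(unique(importance_agg$variable), names(scores))
  if (length(missing))
    stop("no climate change score for: ", paste(sort(missing), collapse = ", "))
  out <- data.frame(
    variable = importance_agg$variable,
    learner_type = importance_agg$learner_type,
    climate_change_score = unname(scores[importance_agg$variable]),
    mean_proportional_importance = importance_agg$mean_proportional)
  out$product <- out$climate_change_score * out$mean_proportional_importance
  overall <- tapply(out$product, out$variable, mean)
  out$overall_mean_product <- as.vector(overall[out$variable])
  # dense descending rank on the per-variable overall mean
  uniq <- sort(unique(out$overall_mean_product), decreasing = TRUE)
  out$rank <- match(out$overall_mean_product, uniq)
  out <- out[order(out$rank, out$variable, out$learner_type), ]
  rownames(out) <- NULL
  class(out) <- c("cip_table", "data.frame")
  out
}

#' Ranked change-importance-product report
#'
#' One row per variable, ordered by overall mean change importance product
#' in descending order (stable sort, ties broken alphabetically and
#' flagged).
#'
#' @param records a `cip_table` from [change_importance_product()].
#' @return data frame `variable, overall_mean_product, rank, tied` ordered
#'   by rank.
#' @export
rank_report <- function(records) {
  stopifnot(nrow(records) >= 1,
            all(c("variable", "overall_mean_product", "rank") %in% names(records)))
  per_var <- unique(as.data.frame(records)[, c("variable",
                                               "overall_mean_product", "rank")])
  class(per_var) <- "data.frame"
  per_var <- per_var[order(-per_var$overall_mean_product, per_var$variable), ]
  tie_counts <- table(per_var$rank)
  per_var$tied <- unname(tie_counts[as.character(per_var$rank)] > 1)
  rownames(per_var) <- NULL
  per_var
}

#' @export
print.cip_table <- function(x, ...) {
  cat("Change importance product (", length(unique(x$variable)),
      " variables x ", length(unique(x$learner_type)), " model families)\n",
      sep = "")
  print.data.frame(utils::head(x, 12), digits = 3)
  if (nrow(x) > 12) cat("  ... ", nrow(x) - 12, " more rows\n", sep = "")
  invisible(x)
}
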