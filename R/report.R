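#' Area under the ROC curve
#'
#' Computed as the Mann-Whitney pair statistic: the probability that a
#' randomly chosen presence scores higher than a randomly chosen absence,
#' with ties counting one half (midrank formulation).
#'
#' @param labels 0/1 vector; both classes must be present.
#' @param scores numeric predictions.
#' @return AUC in `[0, 1]`.
#' @export
auc <- function(labels, scores) {
  stopifnot(length(labels) == length(scores))
  if (!all(labels %in% c(0, 1))) stop("labels must be 0/1")
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  if (n1 == 0 || n0 == 0) stop("AUC undefined: a single class")
  r <- rank(scores)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Coefficient of determination for 0/1 or continuous outcomes
#'
#' Default definition: `1 - SS_res / SS_tot`, well defined against binary
#' labels and the criterion used both for cross-validated model selection
#' and for hold-out goodness of fit. A squared-Pearson-correlation variant
#' is available by flag.
#'
#' @param observed numeric vector with nonzero variance (>= 2 values).
#' @param predicted numeric vector of the same length.
#' @param type `"ss"` (1 - SS_res/SS_tot, default) or `"cor_squared"`.
#' @return a real number, at most 1 (the `"ss"` form can be negative).
#' @export
r_squared <- function(observed, predicted, type = c("ss", "cor_squared")) {
  type <- match.arg(type)
  stopifnot(length(observed) == length(predicted), length(observed) >= 2)
  ss_tot <- sum((observed - mean(observed))^2)
  if (ss_tot == 0) stop("R-squared undefined: observed values have zero variance")
  if (type == "ss") 1 - sum((observed - predicted)^2) / ss_tot
  else {
    if (stats::sd(predicted) == 0) 0
    else stats::cor(observed, predicted)^2
  }
}

#' Hold-out evaluation of ensemble members
#'
#' Scores every member on the balanced hold-out set with both AUC and
#' R-squared, and summarises mean and standard deviation per model family
#' (the Table-1-style goodness-of-fit summary; both metrics are reported
#' for every family so either convention can be read off).
#'
#' @param members list of [tune_and_fit()] members.
#' @param test hold-out occurrence table (both classes present).
#' @return object of class `evaluation_result`: list with `per_member`
#'   (learner_type, bootstrap_id, auc, r_squared) and `summary`
#'   (learner_type, mean/sd of each metric, n_members).
#' @export
evaluate_members <- function(members, test) {
  validate_occurrence(test)
  per <- do.call(rbind, lapply(members, function(m) {
    p <- predict(m, test)
    data.frame(learner_type = m$learner_type,
               bootstrap_id = m$bootstrap_id,
               auc = auc(test$presence, p),
               r_squared = r_squared(test$presence, p))
  }))
  summ <- do.call(rbind, lapply(split(per, per$learner_type), function(g) {
    data.frame(learner_type = g$learner_type[1],
               mean_auc = mean(g$auc),
               sd_auc = if (nrow(g) > 1) stats::sd(g$auc) else 0,
               mean_r_squared = mean(g$r_squared),
               sd_r_squared = if (nrow(g) > 1) stats::sd(g$r_squared) else 0,
               n_members = nrow(g))
  }))
  rownames(summ) <- NULL
  structure(list(per_member = per, summary = summ),
            class = "evaluation_result")
}

#' @export
print.evaluation_result <- function(x, ...) {
  cat("Hold-out goodness of fit (", nrow(x$per_member), " members)\n", sep = "")
  print.data.frame(x$summary, digits = 3)
  invisible(x)
}

#' Ensemble partial dependence of presence probability on one covariate
#'
#' For each value g on an ascending grid spanning the observed covariate
#' range (1st to 99th percentile by default, avoiding extrapolated tails),
#' every record's covariate is set to g and predictions are averaged within
#' each member; the curve reports the mean and standard deviation of those
#' member-level averages across all members of all model families, so the
#' ribbon carries both bootstrap-sample and between-model uncertainty.
#'
#' @param members list of [tune_and_fit()] members (>= 1).
#' @param variable covariate name.
#' @param data occurrence table supplying the evaluation distribution.
#' @param grid_size number of grid points (default 50).
#' @param quantile_trim lower/upper quantiles bounding the grid
#'   (default `c(0.01, 0.99)`).
#' @return object of class `pd_curve`: data frame `variable, grid, mean,
#'   sd, n_members`, with a per-model-family version in
#'   `attr(, "per_learner")`.
#' @export
partial_dependence <- function(members, variable, data, grid_size = 50L,
                               quantile_trim = c(0.01, 0.99)) {
  stopifnot(length(members) >= 1)
  validate_occurrence(data)
  if (!variable %in% names(data)) stop("variable '", variable, "' not in data")
  x <- data[[variable]]
  qs <- stats::quantile(x, quantile_trim, names = FALSE)
  grid <- seq(qs[1], qs[2], length.out = grid_size)
  X <- covariate_matrix(data)
  member_curves <- vapply(members, function(m) {
    Xm <- X[, m$variables, drop = FALSE]
    vapply(grid, function(g) {
      Xg <- Xm
      Xg[, variable] <- g
      mean(predict(m, Xg))
    }, numeric(1))
  }, numeric(length(grid)))
  member_curves <- matrix(member_curves, nrow = length(grid))
  types <- vapply(members, `[[`, character(1), "learner_type")
  out <- data.frame(
    variable = variable,
    grid = grid,
    mean = rowMeans(member_curves),
    sd = apply(member_curves, 1, function(r) if (length(r) > 1) stats::sd(r) else 0),
    n_members = length(members))
  per_learner <- do.call(rbind, lapply(unique(types), function(tt) {
    mc <- member_curves[, types == tt, drop = FALSE]
    data.frame(learner_type = tt, variable = variable, grid = grid,
               mean = rowMeans(mc),
               sd = apply(mc, 1, function(r) if (length(r) > 1) stats::sd(r) else 0),
               n_members = ncol(mc))
  }))
  attr(out, "per_learner") <- per_learner
  class(out) <- c("pd_curve", "data.frame")
  out
}

#' Configure a full species analysis
#'
#' Bundles the inputs and settings of one end-to-end run: occurrence table,
#' expert score sheet, learner list and grids, bootstrap count, hold-out
#' rule, importance settings and the root seed.
#'
#' @param species species label (e.g. `"CES"`, `"WES"`).
#' @param table occurrence table (or path to its CSV).
#' @param score_sheet rater x variable score sheet (or path to its CSV).
#' @param learners subset of `c("rf", "brt", "maxent")`.
#' @param n_bootstrap balanced bootstrap replicates per learner
#'   (default 500).
#' @param presence_fraction hold-out fraction of presences (default 0.2).
#' @param n_test_presence explicit hold-out presence count override.
#' @param vif_threshold collinearity cut (default 10).
#' @param grids named list of tuning grids per learner (`NULL` entries use
#'   [default_grid()]).
#' @param cv_folds cross-validation folds (default 10).
#' @param n_permutations shuffles per covariate for permutation importance
#'   (default 5).
#' @param pd_variables covariates for partial-dependence curves; `NULL`
#'   skips the stage (curves for top-ranked variables can be computed
#'   afterwards from kept members).
#' @param pd_grid_size grid points per curve.
#' @param keep_members keep fitted members in the returned bundle (memory
#'   grows with `n_bootstrap`; default keeps them only for small runs).
#' @param seed root seed for the whole run.
#' @return list of class `species_config`.
#' @export
species_config <- function(species, table, score_sheet,
                           learners = c("rf", "brt", "maxent"),
                           n_bootstrap = 500L,
                           presence_fraction = 0.2,
                           n_test_presence = NULL,
                           vif_threshold = 10,
                           grids = list(),
                           cv_folds = 10L,
                           n_permutations = 5L,
                           pd_variables = NULL,
                           pd_grid_size = 50L,
                           keep_members = n_bootstrap <= 50,
                           seed = 1L) {
  if (is.character(table)) table <- utils::read.csv(table, check.names = FALSE)
  if (is.character(score_sheet))
    score_sheet <- utils::read.csv(score_sheet, row.names = 1, check.names = FALSE)
  validate_occurrence(table)
  learners <- match.arg(learners, c("rf", "brt", "maxent"), several.ok = TRUE)
  structure(list(species = species, table = table, score_sheet = score_sheet,
                 learners = learners, n_bootstrap = as.integer(n_bootstrap),
                 presence_fraction = presence_fraction,
                 n_test_presence = n_test_presence,
                 vif_threshold = vif_threshold, grids = grids,
                 cv_folds = as.integer(cv_folds),
                 n_permutations = as.integer(n_permutations),
                 pd_variables = pd_variables,
                 pd_grid_size = as.integer(pd_grid_size),
                 keep_members = keep_members,
                 seed = as.integer(seed)),
            class = "species_config")
}

#' Run the full habitat climate-sensitivity analysis for one species
#'
#' Executes the pipeline end to end: VIF collinearity screening, balanced
#' hold-out, balanced bootstraps, per-bootstrap tuning and fitting of each
#' ensemble member family, per-member variable importance, aggregation,
#' the change importance product against the expert score sheet, hold-out
#' evaluation and (optionally) ensemble partial-dependence curves. Every
#' stage draws a child seed from the root seed, so reruns with the same
#' config produce identical results.
#'
#' @param config a [species_config()].
#' @param out_dir optional directory; when given, all result tables plus a
#'   machine-readable run manifest are written there as CSV/JSON.
#' @param verbose print per-stage progress.
#' @return object of class `report_bundle`: `vif_report`, `split`,
#'   `importance` (long records), `importance_agg`, `cip`, `ranking`,
#'   `evaluation`, `partial_dependence` (list of curves or `NULL`),
#'   `members` (if kept), `manifest`.
#' @export
run_species_analysis <- function(config, out_dir = NULL, verbose = FALSE) {
  stopifnot(inherits(config, "species_config"))
  say <- function(...) if (verbose) message(sprintf(...))
  t0 <- proc.time()[["elapsed"]]

  say("[vif] screening %d covariates", ncol(config$table) - 2L)
  vif_rep <- filter_by_vif(config$table, threshold = config$vif_threshold)
  table <- config$table[, c("id", "presence", vif_rep$retained)]

  say("[holdout] fraction %.2f", config$presence_fraction)
  split <- make_holdout(table, presence_fraction = config$presence_fraction,
                        seed = child_seed(config$seed, "split"),
                        n_test_presence = config$n_test_presence)

  scores <- average_scores(config$score_sheet)

  specs <- lapply(config$learners, function(lt)
    learner_spec(lt, grid = config$grids[[lt]], cv_folds = config$cv_folds))
  names(specs) <- config$learners

  imp_records <- vector("list", config$n_bootstrap * length(specs))
  eval_rows <- vector("list", config$n_bootstrap * length(specs))
  kept <- if (config$keep_members) vector("list", config$n_bootstrap * length(specs))
  pd_accum <- NULL
  pd_grids <- NULL
  if (!is.null(config$pd_variables)) {
    pd_grids <- lapply(config$pd_variables, function(v) {
      qs <- stats::quantile(split$train[[v]], c(0.01, 0.99), names = FALSE)
      seq(qs[1], qs[2], length.out = config$pd_grid_size)
    })
    names(pd_grids) <- config$pd_variables
    pd_accum <- list()
  }
  n_excluded <- 0L
  slot <- 0L
  test_ok <- length(unique(split$test$presence)) == 2

  for (b in seq_len(config$n_bootstrap)) {
    boot <- draw_bootstrap(split$train, b, seed = child_seed(config$seed, "boots"))
    for (lt in config$learners) {
      slot <- slot + 1L
      member <- tune_and_fit(boot, specs[[lt]],
                             seed = child_seed(config$seed, paste0("fit-", lt), b))
      rec <- withCallingHandlers(
        member_importance(member, data = boot$records,
                          n_permutations = config$n_permutations,
                          seed = child_seed(config$seed, paste0("imp-", lt), b)),
        warning = function(w) invokeRestart("muffleWarning"))
      if (is.null(rec)) n_excluded <- n_excluded + 1L else imp_records[[slot]] <- rec
      if (test_ok) {
        p <- predict(member, split$test)
        eval_rows[[slot]] <- data.frame(
          learner_type = lt, bootstrap_id = b,
          auc = auc(split$test$presence, p),
          r_squared = r_squared(split$test$presence, p))
      }
      if (!is.null(pd_accum)) {
        Xm <- covariate_matrix(split$train)[, member$variables, drop = FALSE]
        for (v in config$pd_variables) {
          curve <- vapply(pd_grids[[v]], function(g) {
            Xg <- Xm; Xg[, v] <- g; mean(predict(member, Xg))
          }, numeric(1))
          pd_accum[[v]] <- rbind(pd_accum[[v]],
                                 data.frame(learner_type = lt, t(curve)))
        }
      }
      if (config$keep_members) kept[[slot]] <- member
    }
    if (verbose && b %% 50L == 0L)
      say("[fit] bootstrap %d/%d (%.0fs elapsed)", b, config$n_bootstrap,
          proc.time()[["elapsed"]] - t0)
  }

  importance <- do.call(rbind, imp_records)
  importance_agg <- aggregate_importance(importance)
  cip <- change_importance_product(importance_agg, scores)
  ranking <- rank_report(cip)
  evaluation <- if (test_ok) {
    per <- do.call(rbind, eval_rows)
    summ <- do.call(rbind, lapply(split(per, per$learner_type), function(g) {
      data.frame(learner_type = g$learner_type[1],
                 mean_auc = mean(g$auc),
                 sd_auc = if (nrow(g) > 1) stats::sd(g$auc) else 0,
                 mean_r_squared = mean(g$r_squared),
                 sd_r_squared = if (nrow(g) > 1) stats::sd(g$r_squared) else 0,
                 n_members = nrow(g))
    }))
    rownames(summ) <- NULL
    structure(list(per_member = per, summary = summ), class = "evaluation_result")
  }

  pd_curves <- NULL
  if (!is.null(pd_accum)) {
    pd_curves <- lapply(config$pd_variables, function(v) {
      mat <- as.matrix(pd_accum[[v]][, -1, drop = FALSE])
      out <- data.frame(variable = v, grid = pd_grids[[v]],
                        mean = colMeans(mat),
                        sd = apply(mat, 2, function(col)
                          if (length(col) > 1) stats::sd(col) else 0),
                        n_members = nrow(mat))
      rownames(out) <- NULL
      class(out) <- c("pd_curve", "data.frame")
      out
    })
    names(pd_curves) <- config$pd_variables
  }

  n_members <- config$n_bootstrap * length(config$learners)
  boot_size <- 2L * sum(split$train$presence == 1)
  manifest <- list(
    species = config$species,
    seed = config$seed,
    n_records = nrow(config$table),
    n_presence = sum(config$table$presence == 1),
    n_absence = sum(config$table$presence == 0),
    covariates_input = ncol(config$table) - 2L,
    covariates_retained = length(vif_rep$retained),
    covariates_removed = nrow(vif_rep$removed),
    n_train_records = nrow(split$train),
    n_train_presence = sum(split$train$presence == 1),
    n_test_records = nrow(split$test),
    n_test_presence = sum(split$test$presence == 1),
    bootstrap_size = boot_size,
    n_bootstrap = config$n_bootstrap,
    learners = config$learners,
    n_members = n_members,
    n_members_excluded_from_importance = n_excluded,
    importance_rows = nrow(importance),
    importance_checksum = signif(sum(importance$proportional) +
                                   sum(importance_agg$mean_proportional), 12),
    cip_max = max(cip$overall_mean_product),
    test_train_id_overlap = length(intersect(split$test$id, split$train$id)))

  bundle <- structure(
    list(species = config$species, vif_report = vif_rep, split = split,
         importance = importance, importance_agg = importance_agg,
         scores = scores, cip = cip, ranking = ranking,
         evaluation = evaluation, partial_dependence = pd_curves,
         members = if (config$keep_members) kept,
         manifest = manifest, config = config),
    class = "report_bundle")
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  say("[done] %d members in %.0fs", n_members, proc.time()[["elapsed"]] - t0)
  bundle
}

#' Write a report bundle's tables and manifest to a directory
#'
#' @param bundle a [run_species_analysis()] result.
#' @param out_dir output directory (created if absent).
#' @return `out_dir`, invisibly.
#' @export
write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  w <- function(df, name)
    utils::write.csv(df, file.path(out_dir, name), row.names = FALSE)
  w(bundle$vif_report$vif, "vif_final.csv")
  w(bundle$vif_report$removed, "vif_removed.csv")
  roles <- rbind(data.frame(record_id = bundle$split$train$id, role = "train"),
                 data.frame(record_id = bundle$split$test$id, role = "test"))
  w(roles, "split_membership.csv")
  w(bundle$importance, "importance_raw.csv")
  w(bundle$importance_agg, "importance_agg.csv")
  w(as.data.frame(bundle$cip), "cip.csv")
  w(bundle$ranking, "cip_ranking.csv")
  if (!is.null(bundle$evaluation)) {
    w(bundle$evaluation$per_member, "evaluation_per_member.csv")
    w(bundle$evaluation$summary, "evaluation_summary.csv")
  }
  if (!is.null(bundle$partial_dependence))
    w(do.call(rbind, lapply(bundle$partial_dependence, as.data.frame)),
      "partial_dependence.csv")
  jsonlite::write_json(bundle$manifest,
                       file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}

#' @export
print.report_bundle <- function(x, ...) {
  m <- x$manifest
  cat("Habitat climate-sensitivity analysis: ", m$species, "\n", sep = "")
  cat("  records: ", m$n_records, " (", m$n_presence, " presence / ",
      m$n_absence, " absence)\n", sep = "")
  cat("  covariates: ", m$covariates_retained, " retained of ",
      m$covariates_input, " (VIF screening)\n", sep = "")
  cat("  hold-out: ", m$n_test_records, " records; bootstraps: ",
      m$n_bootstrap, " x ", length(m$learners), " learners = ",
      m$n_members, " members\n", sep = "")
  cat("  top of ranking:\n")
  print.data.frame(utils::head(x$ranking, 5), digits = 3)
  invisible(x)
}
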