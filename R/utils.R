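#' Derive a reproducible child seed for a pipeline stage
#'
#' A single root seed drives the whole analysis; each stage (simulation,
#' hold-out, bootstrap b, fold assignment, ...) draws its own child seed so
#' that stages are reproducible independently of how many random draws the
#' other stages consume.
#'
#' @param seed integer root seed.
#' @param stage character stage label (e.g. `"holdout"`, `"bootstrap"`).
#' @param index optional integer sub-index (e.g. the bootstrap id).
#' @return an integer seed in `[1, 2^31 - 2]`.
#' @export
child_seed <- function(seed, stage, index = 0L) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  chars <- utf8ToInt(stage)
  h <- sum(chars * seq_along(chars)) %% 2147483647
  # 64-bit-safe mixed congruential step; all intermediates < 2^53
  x <- (as.numeric(seed) %% 2147483647) * 69069 + h * 10007 + as.numeric(index) * 104729 + 1
  as.integer(x %% 2147483646) + 1L
}

#' @keywords internal
`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract the covariate matrix from an occurrence table
#' @keywords internal
covariate_matrix <- function(table) {
  cols <- setdiff(names(table), c("id", "presence"))
  as.matrix(table[, cols, drop = FALSE])
}

#' Validate an occurrence table
#'
#' An occurrence table is a data frame with columns `id`, `presence`
#' (strictly 0/1) and one numeric column per environmental covariate.
#'
#' @param table data frame to validate.
#' @return the table, invisibly, if valid; otherwise an error.
#' @export
validate_occurrence <- function(table) {
  if (!is.data.frame(table)) stop("occurrence table must be a data frame")
  if (!all(c("id", "presence") %in% names(table)))
    stop("occurrence table needs 'id' and 'presence' columns")
  if (anyDuplicated(table$id)) stop("record ids must be unique")
  if (!all(table$presence %in% c(0, 1)))
    stop("'presence' must be strictly binary (0/1)")
  covs <- setdiff(names(table), c("id", "presence"))
  if (anyDuplicated(covs)) stop("covariate names must be unique")
  for (v in covs) {
    if (!is.numeric(table[[v]])) stop("covariate '", v, "' is not numeric")
    if (anyNA(table[[v]])) stop("covariate '", v, "' has missing values")
  }
  invisible(table)
}
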