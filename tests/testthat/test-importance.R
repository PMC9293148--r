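test_that("permutation importance behaves at its analytic anchors", {
  set.seed(41)
  n <- 200
  x1 <- c(rnorm(n / 2, 4), rnorm(n / 2, -4))  # perfectly separating
  tab <- data.frame(id = sprintf("r%03d", 1:n),
                    presence = rep(c(1, 0), each = n / 2),
                    x1 = x1, x2 = rnorm(n))
  boot <- draw_bootstrap(tab, 1, seed = 1)
  m <- tune_and_fit(boot, learner_spec("rf", grid = tiny_grids()$rf,
                                       cv_folds = 5), seed = 2)

  # degenerate zero-permutation path: identity, importance 0 everywhere
  imp0 <- permutation_importance(m, boot$records, n_permutations = 0)
  expect_identical(unname(imp0), c(0, 0))

  # single perfectly predictive covariate: baseline AUC 1, permuted ~ 0.5
  imp <- permutation_importance(m, boot$records, n_permutations = 10, seed = 3)
  expect_equal(unname(imp["x1"]), 0.5, tolerance = 0.1)
  expect_lt(abs(imp["x2"]), 0.05)  # unused covariate ~ 0 within MC error

  # single-class evaluation data is rejected
  only_pres <- boot$records[boot$records$presence == 1, ]
  expect_error(permutation_importance(m, only_pres), "single class")
})

test_that("BRT relative influence concentrates on the only informative split", {
  set.seed(42)
  n <- 300
  tab <- data.frame(id = sprintf("r%03d", 1:n),
                    presence = rep(c(1, 0), each = n / 2),
                    x1 = c(rnorm(n / 2, 3), rnorm(n / 2, -3)),
                    x2 = rnorm(n), x3 = rnorm(n))
  boot <- draw_bootstrap(tab, 1, seed = 1)
  grid <- data.frame(eta = 0.3, max_depth = 1L, nrounds = 20L)  # stumps
  m <- tune_and_fit(boot, learner_spec("brt", grid = grid, cv_folds = 5),
                    seed = 2)
  infl <- brt_relative_influence(m)
  expect_equal(sum(infl), 100, tolerance = 1e-9)  # always percentages
  expect_gt(infl["x1"], 99)                        # all stumps split on x1

  # cross-check against the library's own gain summary (independent route)
  gain <- xgboost::xgb.importance(model = m$model)
  lib <- setNames(rep(0, 3), c("x1", "x2", "x3"))
  lib[gain$Feature] <- 100 * gain$Gain
  expect_equal(unname(infl[names(lib)]), unname(lib), tolerance = 1e-6)

  # members without gain records are rejected
  m0 <- m; m0$model <- structure(list(base_score = 0.5),
                                 class = "constant_model")
  expect_error(brt_relative_influence(m0), "no gain records")
  mrf <- m; mrf$learner_type <- "rf"
  expect_error(brt_relative_influence(mrf), "BRT members only")
})

test_that("proportional importance is a simplex projection with clipping", {
  expect_equal(proportional_importance(c(a = 2, b = 1, c = 1)),
               c(a = 0.5, b = 0.25, c = 0.25))
  expect_equal(proportional_importance(c(a = -0.01, b = 1)), c(a = 0, b = 1))
  expect_error(proportional_importance(c(a = 0, b = -2)), "all raw importances")
  set.seed(43)
  for (i in 1:20) {
    raw <- rnorm(sample(2:10, 1))
    if (all(raw <= 0)) raw[1] <- abs(raw[1]) + 0.1
    prop <- proportional_importance(raw)
    expect_equal(sum(prop), 1, tolerance = 1e-9)
    expect_true(all(prop >= 0))
  }
})

test_that("aggregation matches a brute-force group-by on a small toy", {
  records <- data.frame(
    learner_type = rep(c("rf", "brt"), each = 6),
    bootstrap_id = rep(rep(1:3, each = 2), 2),
    variable = rep(c("a", "b"), 6),
    raw = 1,
    proportional = c(0.6, 0.4, 0.7, 0.3, 0.5, 0.5,
                     0.9, 0.1, 0.8, 0.2, 0.7, 0.3))
  agg <- aggregate_importance(records)
  brute <- aggregate(proportional ~ learner_type + variable, records,
                     function(v) c(mean(v), sd(v)))
  for (i in seq_len(nrow(brute))) {
    row <- agg[agg$learner_type == brute$learner_type[i] &
                 agg$variable == brute$variable[i], ]
    expect_equal(row$mean_proportional, brute$proportional[i, 1])
    expect_equal(row$sd_proportional, brute$proportional[i, 2])
  }
  # per-learner means still sum to 1 across variables (linearity)
  sums <- tapply(agg$mean_proportional, agg$learner_type, sum)
  expect_equal(as.numeric(sums), c(1, 1), tolerance = 1e-9)

  # identical records have zero dispersion
  same <- records[c(1, 1, 1), ]; same$bootstrap_id <- 1:3
  expect_identical(aggregate_importance(same)$sd_proportional, 0)
})

test_that("member_importance excludes zero-information members gracefully", {
  boot <- toy_bootstrap(seed = 44)
  m <- tune_and_fit(boot, learner_spec("maxent",
                                       grid = data.frame(reg_mult = 1e6),
                                       cv_folds = 5), seed = 1)
  # constant predictions: every permuted AUC equals the baseline 0.5
  expect_warning(rec <- member_importance(m, boot$records, seed = 2),
                 "excluded")
  expect_null(rec)
})
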