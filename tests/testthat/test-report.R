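test_that("AUC equals the all-pairs Mann-Whitney statistic", {
  expect_identical(auc(c(1, 1, 0, 0), c(0.9, 0.4, 0.6, 0.1)), 0.75)
  expect_identical(auc(c(1, 0), c(1, 0)), 1)        # perfect separation
  expect_identical(auc(c(1, 0, 1, 0), rep(0.3, 4)), 0.5)  # all tied
  expect_error(auc(c(1, 1), c(0.2, 0.3)), "single class")
  # exact equivalence with the brute-force pair count, ties included
  set.seed(61)
  for (i in 1:10) {
    n <- sample(10:200, 1)
    labels <- rbinom(n, 1, 0.4)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    scores <- sample(seq(0, 1, 0.05), n, replace = TRUE)  # force ties
    expect_equal(auc(labels, scores), auc_bruteforce(labels, scores),
                 tolerance = 1e-12)
  }
})

test_that("R-squared follows 1 - SS_res/SS_tot with a correlation variant", {
  expect_identical(r_squared(c(0, 1, 1, 0), c(0, 1, 1, 0)), 1)
  expect_identical(r_squared(c(0, 1, 1, 0), rep(0.5, 4)), 0)
  expect_identical(r_squared(c(0, 1, 1, 0), c(0.25, 0.75, 0.75, 0.25)), 0.75)
  expect_error(r_squared(c(1, 1, 1), c(0.1, 0.2, 0.3)), "zero variance")
  set.seed(62)
  o <- rbinom(30, 1, 0.5); p <- runif(30)
  expect_equal(r_squared(o, p, type = "cor_squared"), cor(o, p)^2)
  expect_identical(r_squared(o, rep(0.4, 30), type = "cor_squared"), 0)
})

test_that("partial dependence recovers shape, flatness and zero SD", {
  cfg <- sim_config(300, 600, c("x1", "x2"),
                    driver_coefficients = c(x1 = 2.5), seed = 63)
  ds <- simulate_dataset(cfg)
  boot <- draw_bootstrap(ds$table, 1, seed = 64)
  m <- tune_and_fit(boot, learner_spec("maxent",
                                       grid = data.frame(reg_mult = 0.5),
                                       cv_folds = 5), seed = 65)
  pd <- partial_dependence(list(m), "x1", ds$table, grid_size = 25)
  expect_identical(nrow(pd), 25L)
  expect_true(all(diff(pd$grid) > 0))          # strictly ascending grid
  expect_true(all(pd$mean >= 0 & pd$mean <= 1))
  expect_identical(unname(pd$sd), rep(0, 25))  # single member: SD 0
  # the generating shape is increasing in the driver (up to link scale)
  expect_gt(cor(pd$grid, pd$mean, method = "spearman"), 0.95)

  # a member that never uses the variable yields a flat curve
  pd2 <- partial_dependence(list(m), "x2", ds$table, grid_size = 10)
  expect_lt(diff(range(pd2$mean)), 1e-6)
  expect_error(partial_dependence(list(m), "nope", ds$table), "not in data")
})

test_that("the full pipeline produces a consistent, reproducible bundle", {
  cfg <- two_driver_config(n_presence = 80, n_absence = 400, seed = 66)
  ds <- simulate_dataset(cfg)
  sheet <- generate_score_sheet(paste0("x", 1:6), 4, seed = 67,
                                forced = c(x1 = 3, x4 = 0))
  sc <- species_config("TOY", ds$table, sheet, n_bootstrap = 2,
                       grids = tiny_grids(), cv_folds = 5,
                       n_permutations = 2, pd_variables = "x1",
                       pd_grid_size = 10, seed = 68)
  b <- run_species_analysis(sc)

  # manifest counts: bootstraps x learners members, balanced bootstrap size
  expect_identical(b$manifest$n_members, 6L)
  expect_identical(b$manifest$bootstrap_size,
                   2L * sum(b$split$train$presence == 1))
  expect_identical(b$manifest$n_test_presence, 16L)  # floor(0.2 * 80)
  # evaluation strictly on hold-out: no id overlap with training
  expect_identical(b$manifest$test_train_id_overlap, 0L)
  # importance proportions are a simplex per member
  sums <- tapply(b$importance$proportional,
                 interaction(b$importance$learner_type,
                             b$importance$bootstrap_id), sum)
  expect_true(all(abs(sums - 1) < 1e-9))
  # partial dependence carries cross-member dispersion
  expect_identical(nrow(b$partial_dependence$x1), 10L)
  expect_identical(unique(b$partial_dependence$x1$n_members), 6L)

  # rerun with the same config: identical manifest
  b2 <- run_species_analysis(sc)
  expect_identical(b$manifest, b2$manifest)
  expect_identical(b$cip, b2$cip)

  # single bootstrap, single learner: all downstream tables single-row groups
  sc1 <- species_config("TOY1", ds$table, sheet, n_bootstrap = 1,
                        learners = "rf", grids = tiny_grids(), cv_folds = 5,
                        n_permutations = 2, seed = 69)
  b1 <- run_species_analysis(sc1)
  expect_identical(b1$manifest$n_members, 1L)
  expect_true(all(b1$importance_agg$n_bootstraps == 1L))
  expect_identical(nrow(b1$evaluation$summary), 1L)
})

test_that("bundles round-trip their tables and manifest to disk", {
  cfg <- two_driver_config(n_presence = 60, n_absence = 240, seed = 70)
  ds <- simulate_dataset(cfg)
  sheet <- generate_score_sheet(paste0("x", 1:6), 3, seed = 71)
  sc <- species_config("IO", ds$table, sheet, n_bootstrap = 1,
                       learners = c("rf", "brt"), grids = tiny_grids(),
                       cv_folds = 5, n_permutations = 2, seed = 72)
  out <- file.path(tempdir(), "icehab-io-test")
  on.exit(unlink(out, recursive = TRUE))
  b <- run_species_analysis(sc, out_dir = out)
  expect_true(all(file.exists(file.path(
    out, c("vif_final.csv", "split_membership.csv", "importance_raw.csv",
           "importance_agg.csv", "cip.csv", "cip_ranking.csv",
           "evaluation_summary.csv", "manifest.json")))))
  man <- jsonlite::read_json(file.path(out, "manifest.json"))
  expect_identical(man$n_members, b$manifest$n_members)
  roles <- read.csv(file.path(out, "split_membership.csv"))
  expect_identical(nrow(roles), nrow(ds$table))
})
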