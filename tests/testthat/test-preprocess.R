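make_table <- function(X) {
  data.frame(id = sprintf("r%03d", seq_len(nrow(X))),
             presence = rep_len(c(1, 0), nrow(X)), X)
}

test_that("VIF matches the closed form and flags exact collinearity", {
  # sample-orthogonal covariates: R^2 = 0 exactly, VIF = 1
  X <- MASS::mvrnorm(50, mu = c(0, 0), Sigma = diag(2), empirical = TRUE)
  colnames(X) <- c("a", "b")
  v <- compute_vif(make_table(X))
  expect_equal(v$vif, c(1, 1), tolerance = 1e-10)

  # empirical r = 0.9 with an orthogonal third: VIF = 1/(1 - 0.81)
  S <- rbind(c(1, 0.9, 0), c(0.9, 1, 0), c(0, 0, 1))
  X3 <- MASS::mvrnorm(200, mu = rep(0, 3), Sigma = S, empirical = TRUE)
  colnames(X3) <- c("x1", "x2", "x3")
  v3 <- compute_vif(make_table(X3))
  expect_equal(v3$vif[1:2], rep(1 / (1 - 0.81), 2), tolerance = 1e-8)

  # exact linear dependence is reported as unbounded, not overflow
  set.seed(1)
  Z <- matrix(rnorm(200), ncol = 2, dimnames = list(NULL, c("x1", "x2")))
  Z <- cbind(Z, x3 = Z[, "x1"] + Z[, "x2"])
  vz <- compute_vif(make_table(Z))
  expect_true(vz$unbounded[vz$variable == "x3"])
  expect_identical(vz$vif[vz$variable == "x3"], Inf)
})

test_that("VIF agrees with brute-force OLS on random instances", {
  for (s in 1:5) {
    set.seed(s)
    n <- 80
    X <- matrix(rnorm(n * 6), ncol = 6)
    X[, 6] <- 0.7 * X[, 1] + 0.5 * X[, 2] + rnorm(n, sd = 0.4)
    colnames(X) <- paste0("v", 1:6)
    expect_equal(compute_vif(make_table(X))$vif, vif_bruteforce(X),
                 tolerance = 1e-8)
  }
})

test_that("VIF rejects degenerate inputs", {
  set.seed(2)
  X <- cbind(a = rnorm(20), b = rep(1, 20))
  expect_error(compute_vif(make_table(X)), "constant")
  expect_error(compute_vif(make_table(matrix(rnorm(20), ncol = 1,
                                             dimnames = list(NULL, "a")))),
               "at least 2")
})

test_that("iterative VIF filtering removes collinear variables stepwise", {
  set.seed(3)
  X <- matrix(rnorm(500), ncol = 5, dimnames = list(NULL, paste0("v", 1:5)))
  tab <- make_table(X)
  rep0 <- filter_by_vif(tab)
  expect_identical(rep0$retained, paste0("v", 1:5))  # no collinearity
  expect_identical(nrow(rep0$removed), 0L)

  # an exact duplicate has unbounded VIF and is removed first; 4 retained
  Xd <- cbind(X[, 1:4], v4b = X[, 4])
  repd <- filter_by_vif(make_table(Xd))
  expect_length(repd$retained, 4L)
  expect_true(repd$removed$variable[1] %in% c("v4", "v4b"))
  expect_identical(repd$removed$variable[1], "v4")  # alphabetical tie-break
  expect_identical(repd$threshold, 10)              # the conventional default

  # idempotence: filtering an already-filtered table removes nothing
  kept <- make_table(Xd[, repd$retained])
  expect_identical(nrow(filter_by_vif(kept)$removed), 0L)

  # every retained variable's final VIF is at or below the threshold
  expect_true(all(filter_by_vif(make_table(Xd))$vif$vif <= 10))
})

test_that("hold-out reproduces the balanced-count arithmetic", {
  set.seed(4)
  n_pres <- 4911; n_abs <- 9000
  tab <- data.frame(id = sprintf("r%05d", seq_len(n_pres + n_abs)),
                    presence = rep(c(1, 0), c(n_pres, n_abs)),
                    x1 = rnorm(n_pres + n_abs), x2 = rnorm(n_pres + n_abs))
  sp <- make_holdout(tab, presence_fraction = 0.2, seed = 11)
  expect_identical(sum(sp$test$presence == 1), 982L)   # floor(0.2 * 4911)
  expect_identical(sum(sp$test$presence == 0), 982L)
  expect_identical(nrow(sp$test), 1964L)
  expect_identical(sum(sp$train$presence == 1), 3929L)
  expect_length(intersect(sp$test$id, sp$train$id), 0L)

  # explicit-count override and the degenerate zero fraction
  sp38 <- make_holdout(tab, seed = 11, n_test_presence = 38)
  expect_identical(nrow(sp38$test), 76L)
  sp0 <- make_holdout(tab, presence_fraction = 0, seed = 11)
  expect_identical(nrow(sp0$test), 0L)
  expect_identical(nrow(sp0$train), nrow(tab))

  # requested balance beyond the absence pool is rejected
  small <- tab[c(1:50, n_pres + (1:10)), ]
  expect_error(make_holdout(small, n_test_presence = 20, seed = 1), "exceeds")
})

test_that("balanced bootstraps keep all presences and a 1:1 class ratio", {
  set.seed(5)
  tab <- data.frame(id = sprintf("r%04d", 1:1200),
                    presence = rep(c(1, 0), c(200, 1000)),
                    x1 = rnorm(1200))
  for (b in 1:3) {
    bs <- draw_bootstrap(tab, b, seed = 7)
    expect_identical(nrow(bs$records), 400L)  # 2 x presence count
    expect_setequal(bs$records$id[bs$records$presence == 1],
                    tab$id[tab$presence == 1])
    expect_identical(sum(bs$records$presence == 0), 200L)
    expect_false(anyDuplicated(bs$records$id[bs$records$presence == 0]) > 0)
  }
  # determinism: the same seed selects the same absences
  expect_identical(draw_bootstrap(tab, 2, seed = 7)$records,
                   draw_bootstrap(tab, 2, seed = 7)$records)
  expect_false(identical(draw_bootstrap(tab, 1, seed = 7)$records,
                         draw_bootstrap(tab, 2, seed = 7)$records))

  # with-replacement fallback when absences are scarcer than presences
  scarce <- tab[c(1:100, 201:240), ]
  bs2 <- draw_bootstrap(scarce, 1, seed = 9)
  expect_identical(nrow(bs2$records), 200L)
  expect_identical(sum(bs2$records$presence == 0), 100L)

  # the 1-presence / 1-absence degenerate case is the whole table
  mini <- tab[c(1, 201), ]
  expect_setequal(draw_bootstrap(mini, 1, seed = 1)$records$id, mini$id)
  expect_error(draw_bootstrap(tab[1:5, ], 1, seed = 1), "at least one")
})
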