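# Shared fixtures: small synthetic datasets and one-candidate tuning grids
# keep the model-fitting tests fast while leaving the data conditions
# (imbalance, drivers, collinearity) realistic.

tiny_grids <- function() {
  list(rf = data.frame(mtry = 3L, num_trees = 50L),
       brt = data.frame(eta = 0.1, max_depth = 2L, nrounds = 50L),
       maxent = data.frame(reg_mult = 1))
}

two_driver_config <- function(n_presence = 100, n_absence = 500, p = 6,
                              seed = 42) {
  sim_config(n_presence, n_absence, paste0("x", seq_len(p)),
             driver_coefficients = c(x1 = 2, x2 = -1.5), seed = seed)
}

# a balanced bootstrap sample ready for tune_and_fit
toy_bootstrap <- function(n_presence = 100, n_absence = 500, p = 6,
                          seed = 42, bootstrap_id = 1L) {
  ds <- simulate_dataset(two_driver_config(n_presence, n_absence, p, seed))
  draw_bootstrap(ds$table, bootstrap_id, seed = seed)
}

# brute-force AUC: count concordant pairs over every (presence, absence) pair
auc_bruteforce <- function(labels, scores) {
  sp <- scores[labels == 1]
  sa <- scores[labels == 0]
  total <- 0
  for (i in seq_along(sp)) {
    total <- total + sum(sp[i] > sa) + 0.5 * sum(sp[i] == sa)
  }
  total / (length(sp) * length(sa))
}

# brute-force VIF through R's canonical lm() interface
vif_bruteforce <- function(X) {
  vapply(seq_len(ncol(X)), function(j) {
    df <- as.data.frame(X)
    names(df) <- paste0("v", seq_len(ncol(X)))
    fit <- stats::lm(stats::reformulate(paste0("v", setdiff(seq_len(ncol(X)), j)),
                                        response = paste0("v", j)), data = df)
    1 / (1 - summary(fit)$r.squared)
  }, numeric(1))
}
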