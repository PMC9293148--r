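#' Declare a maximum-entropy feature expansion
#'
#' The maximum-entropy learner models the presence density over the
#' background as an exponential family on a deterministic feature expansion
#' of the covariates. Supported feature classes: `linear` (x), `quadratic`
#' (x^2), `product` (pairwise x_i x_j) and `hinge` (max(0, x - k) and
#' max(0, k - x) at quantile knots). Features are standardised against the
#' background by default so the L1 penalty treats them comparably.
#'
#' @param classes subset of `c("linear","quadratic","hinge","product")`.
#' @param n_hinge number of interior quantile knots per direction for hinge
#'   features.
#' @param standardize centre/scale features using background moments.
#' @return object of class `maxent_features` (an unfitted declaration).
#' @export
maxent_features <- function(classes = c("linear", "quadratic"),
                            n_hinge = 4L, standardize = TRUE) {
  classes <- match.arg(classes, c("linear", "quadratic", "hinge", "product"),
                       several.ok = TRUE)
  structure(list(classes = classes, n_hinge = as.integer(n_hinge),
                 standardize = standardize, fitted = FALSE),
            class = "maxent_features")
}

# Bind the declaration to data: compute hinge knots and standardisation
# constants from the background (the available environment).
fit_expansion <- function(expansion, background) {
  stopifnot(inherits(expansion, "maxent_features"))
  background <- as.matrix(background)
  knots <- NULL
  if ("hinge" %in% expansion$classes) {
    probs <- seq(0, 1, length.out = expansion$n_hinge + 2L)
    probs <- probs[-c(1, length(probs))]
    knots <- apply(background, 2, stats::quantile, probs = probs, names = FALSE)
    knots <- matrix(knots, ncol = ncol(background),
                    dimnames = list(NULL, colnames(background)))
  }
  expansion$knots <- knots
  Fb <- expand_features(expansion, background, raw = TRUE)
  if (expansion$standardize) {
    expansion$center <- colMeans(Fb)
    s <- apply(Fb, 2, stats::sd)
    expansion$scale <- ifelse(s > 0, s, 1)
  } else {
    expansion$center <- rep(0, ncol(Fb))
    expansion$scale <- rep(1, ncol(Fb))
  }
  names(expansion$center) <- names(expansion$scale) <- colnames(Fb)
  expansion$feature_names <- colnames(Fb)
  expansion$variables <- colnames(background)
  expansion$fitted <- TRUE
  expansion
}

# Map covariates -> feature matrix. With raw = TRUE no standardisation is
# applied (used while fitting the expansion itself).
expand_features <- function(expansion, X, raw = FALSE) {
  X <- as.matrix(X)
  vars <- colnames(X)
  out <- list()
  if ("linear" %in% expansion$classes) {
    L <- X
    colnames(L) <- vars
    out$linear <- L
  }
  if ("quadratic" %in% expansion$classes) {
    Q <- X^2
    colnames(Q) <- paste0(vars, "^2")
    out$quadratic <- Q
  }
  if ("product" %in% expansion$classes && length(vars) > 1) {
    pairs <- utils::combn(seq_along(vars), 2)
    P <- apply(pairs, 2, function(ij) X[, ij[1]] * X[, ij[2]])
    P <- matrix(P, nrow = nrow(X))
    colnames(P) <- apply(pairs, 2, function(ij)
      paste0(vars[ij[1]], "*", vars[ij[2]]))
    out$product <- P
  }
  if ("hinge" %in% expansion$classes) {
    kn <- expansion$knots
    if (is.null(kn)) stop("hinge features need a fitted expansion")
    H <- list()
    for (v in vars) {
      for (i in seq_len(nrow(kn))) {
        k <- kn[i, v]
        H[[paste0("h(", v, "-", signif(k, 4), ")")]] <- pmax(0, X[, v] - k)
        H[[paste0("h(", signif(k, 4), "-", v, ")")]] <- pmax(0, k - X[, v])
      }
    }
    out$hinge <- do.call(cbind, H)
  }
  Fm <- do.call(cbind, out)
  if (!raw && isTRUE(expansion$fitted))
    Fm <- sweep(sweep(Fm, 2, expansion$center), 2, expansion$scale, "/")
  Fm
}

log_mean_exp <- function(x) {
  m <- max(x)
  m + log(mean(exp(x - m)))
}

#' Fit an L1-regularised maximum-entropy presence/background model
#'
#' Maximises the mean log-density of the presence records under the
#' exponential-family density normalised over the background sample, minus
#' an L1 penalty on the feature weights:
#' `max_w mean_pres(F w) - log mean_bg(exp(F w)) - sum_j lambda_j |w_j|`,
#' with `lambda_j = regularization * s_j / sqrt(n_presence)` where `s_j` is
#' the feature's standard deviation over the presences. The objective is
#' concave; it is solved by accelerated proximal gradient (FISTA) with
#' backtracking to a prox-gradient residual below `tol`. At
#' `regularization = 0` the solution satisfies the maximum-entropy moment
#' constraints: the model-weighted background feature means equal the
#' presence feature means.
#'
#' @param presences covariate matrix (or data frame) of presence records.
#' @param background covariate matrix of background records (here, sampled
#'   absences); at least 2 distinct rows.
#' @param expansion a [maxent_features()] declaration.
#' @param regularization non-negative penalty multiplier.
#' @param tol prox-gradient convergence tolerance (default 1e-6).
#' @param max_iter iteration cap.
#' @return object of class `maxent_fit`: weights (standardised feature
#'   scale), the fitted expansion, log-normaliser over the background, class
#'   sizes, and the regularisation point.
#' @export
fit_maxent <- function(presences, background, expansion = maxent_features(),
                       regularization = 1, tol = 1e-6, max_iter = 20000L) {
  presences <- as.matrix(presences)
  background <- as.matrix(background)
  if (nrow(presences) < 1) stop("need at least one presence record")
  if (nrow(unique(background)) < 2)
    stop("need at least 2 distinct background rows")
  stopifnot(regularization >= 0)
  if (!all(is.finite(presences)) || !all(is.finite(background)))
    stop("non-finite covariate values")

  expansion <- fit_expansion(expansion, background)
  Fp <- expand_features(expansion, presences)
  Fb <- expand_features(expansion, background)
  if (!all(is.finite(Fp)) || !all(is.finite(Fb)))
    stop("non-finite features after expansion")
  k <- ncol(Fb)
  mean_p <- colMeans(Fp)
  sp <- apply(Fp, 2, stats::sd)
  lambda <- regularization * pmax(sp, 1e-3) / sqrt(nrow(Fp))

  # negative concave objective (convex): g(w) = -mean_p.w + log mean_b e^{Fb w}
  grad_g <- function(w) {
    eta <- drop(Fb %*% w)
    wts <- exp(eta - max(eta))
    wts <- wts / sum(wts)
    drop(crossprod(Fb, wts)) - mean_p
  }
  g <- function(w) log_mean_exp(drop(Fb %*% w)) - sum(mean_p * w)

  soft <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
  obj <- function(w, gw) gw + sum(lambda * abs(w))
  w <- numeric(k)
  z <- w
  t_acc <- 1
  L <- 1
  gw <- g(w)
  obj_w <- obj(w, gw)
  res <- Inf
  # FISTA with backtracking and adaptive restart on objective increase
  for (it in seq_len(max_iter)) {
    gz <- if (t_acc == 1) gw else g(z)
    gr <- grad_g(z)
    repeat {
      w_new <- soft(z - gr / L, lambda / L)
      dw <- w_new - z
      gw_new <- g(w_new)
      if (gw_new <= gz + sum(gr * dw) + L / 2 * sum(dw^2) + 1e-12) break
      L <- L * 2
      if (L > 1e14) break
    }
    if (obj(w_new, gw_new) > obj_w + 1e-12 && t_acc > 1) {
      z <- w         # momentum overshoot: restart from the last accepted point
      t_acc <- 1
      next
    }
    res <- L * max(abs(w_new - z))  # prox-gradient mapping norm at z
    t_new <- (1 + sqrt(1 + 4 * t_acc^2)) / 2
    z <- w_new + (t_acc - 1) / t_new * (w_new - w)
    w <- w_new
    gw <- gw_new
    obj_w <- obj(w, gw)
    t_acc <- t_new
    if (res < tol) break
    L <- max(L / 1.5, 1e-8)  # allow the step to grow back
  }
  converged <- res < tol
  if (!converged)
    warning("maxent solver did not reach tolerance ", tol, " in ", max_iter,
            " iterations (residual ", signif(res, 3), "); the objective may ",
            "be unbounded - presences may lie outside the background hull. ",
            "Consider augmenting the background with the presence records ",
            "or increasing the regularization.")
  eta_b <- drop(Fb %*% w)
  structure(
    list(weights = stats::setNames(w, colnames(Fb)),
         expansion = expansion,
         log_z = log_mean_exp(eta_b),
         regularization = regularization,
         n_presence = nrow(presences),
         n_background = nrow(background),
         iterations = it,
         converged = converged),
    class = "maxent_fit")
}

#' Predict probability of presence from a maximum-entropy fit
#'
#' The fitted relative log-density `F(x) w - log Z_bg` is converted to a
#' probability by the logistic transform anchored at the training
#' prevalence: `plogis(eta + qlogis(n_presence / (n_presence +
#' n_background)))`, so a point whose density matches the background average
#' scores the prevalence itself.
#'
#' @param object a `maxent_fit`.
#' @param newdata covariate matrix or data frame.
#' @param ... unused.
#' @return numeric vector of probabilities in `[0, 1]`.
#' @export
predict.maxent_fit <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  miss <- setdiff(object$expansion$variables, colnames(X))
  if (length(miss)) stop("missing covariates: ", paste(miss, collapse = ", "))
  X <- X[, object$expansion$variables, drop = FALSE]
  Fm <- expand_features(object$expansion, X)
  eta <- drop(Fm %*% object$weights) - object$log_z
  prev <- object$n_presence / (object$n_presence + object$n_background)
  stats::plogis(eta + stats::qlogis(prev))
}
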