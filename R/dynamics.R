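# Dynamic-versus-static classification of time-course profiles by
# Gaussian-process model selection.
#
# Two zero-mean GP models are fitted to each normalised profile over the
# transformed time axis, using all replicate observations jointly:
#   dynamic: squared-exponential (RBF) kernel + white noise  (k = 3)
#   static : pure white noise                                (k = 1)
# Model choice uses BIC = k ln(n) - 2 ln(Lhat); a stricter chi-squared(1)
# test is applied to LR = 2 (ln Lhat_RBF - ln Lhat_STATIC).

# ---- marginal likelihood ---------------------------------------------------

# log N(y; 0, K) with K = sf2 * RBF(x; ell) + sn2 * I.
# D2 is the precomputed squared-distance matrix of the transformed times.
gp_loglik <- function(logpar, y, D2) {
  sf2 <- exp(logpar[1]); ell <- exp(logpar[2]); sn2 <- exp(logpar[3])
  n <- length(y)
  K <- sf2 * exp(-0.5 * D2 / ell^2) + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) NULL)
  if (is.null(L)) {
    L <- chol(K + diag(1e-6 * mean(diag(K)), n))
  }
  a <- backsolve(L, forwardsolve(t(L), y))
  -0.5 * sum(y * a) - sum(log(diag(L))) - n / 2 * log(2 * pi)
}

# gradient of gp_loglik with respect to the log-hyperparameters
gp_loglik_grad <- function(logpar, y, D2) {
  sf2 <- exp(logpar[1]); ell <- exp(logpar[2]); sn2 <- exp(logpar[3])
  n <- length(y)
  C <- exp(-0.5 * D2 / ell^2)
  K <- sf2 * C + diag(sn2 + 1e-10, n)
  L <- tryCatch(chol(K), error = function(e) chol(K + diag(1e-6 * mean(diag(K)), n)))
  Kinv <- chol2inv(L)
  a <- Kinv %*% y
  W <- tcrossprod(a) - Kinv   # d loglik / dK = W / 2
  g_sf2 <- 0.5 * sum(W * (sf2 * C))
  g_ell <- 0.5 * sum(W * (sf2 * C * D2 / ell^2))
  g_sn2 <- 0.5 * sum(diag(W)) * sn2
  c(g_sf2, g_ell, g_sn2)
}

#' Bayesian information criterion
#'
#' `bic = k * ln(n) - 2 * loglik`; smaller values indicate the favoured
#' model.
#'
#' @param k Number of free parameters (3 for the dynamic GP, 1 for the
#'   static model).
#' @param n Number of observations (replicates x time points).
#' @param loglik Maximised log-likelihood in nats.
#' @return BIC value (dimensionless). Vectorised over all arguments.
#' @export
bic <- function(k, n, loglik) {
  if (any(n < 1)) abort("n must be at least 1")
  if (any(k < 0)) abort("k must be non-negative")
  k * log(n) - 2 * loglik
}

#' Fit the dynamic and static Gaussian-process models to one profile
#'
#' The profile's normalised, mean-centred values are modelled as a zero-mean
#' GP over the transformed time axis, with every replicate observation
#' entering jointly (`n = replicates x time points`). The dynamic model's
#' three hyperparameters (signal variance, lengthscale, noise variance) are
#' optimised by bounded quasi-Newton with analytic gradients from multiple
#' starts; the static model's single noise variance has the closed form
#' `mean(y^2)`. One start is pinned at the static optimum (zero signal
#' variance bound), which guarantees the dynamic likelihood is never below
#' the static one.
#'
#' @param times Time points in minutes (length >= 3, strictly increasing).
#' @param values Numeric matrix `replicates x time points` of normalised,
#'   centred values, or a vector for a single replicate.
#' @param time_transform Passed to [transform_times()].
#' @param n_restarts Number of optimiser starts (default 5).
#' @param seed Seed for the randomised starts (default 1).
#' @return List with elements `dynamic` and `static`, each a `gp_fit` list:
#'   `model`, `log_marginal_likelihood`, `hyperparams`, `k`, `n`, `bic`.
#' @export
fit_gp_models <- function(times, values,
                          time_transform = "log2min",
                          n_restarts = 5, seed = 1) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  if (length(times) < 3) abort("at least 3 time points are required")
  if (any(diff(times) <= 0)) abort("times must be strictly increasing")
  if (ncol(values) != length(times)) {
    abort("values must have one column per time point")
  }
  x <- transform_times(times, time_transform)
  reps <- nrow(values)
  xx <- rep(x, each = reps)
  y <- as.numeric(values)            # column-major: replicates within time
  n <- length(y)
  D2 <- outer(xx, xx, "-")^2

  # static: zero-mean white noise, closed-form MLE
  s2_hat <- max(mean(y^2), 1e-12)
  ll_static <- -n / 2 * (log(2 * pi * s2_hat) + 1)
  static_fit <- structure(list(
    model = "static", log_marginal_likelihood = ll_static,
    hyperparams = c(sigma_f2 = 0, lengthscale = NA_real_, sigma_n2 = s2_hat),
    k = 1L, n = n, bic = bic(1, n, ll_static)
  ), class = "gp_fit")

  # dynamic: multi-start bounded quasi-Newton on log-hyperparameters
  span <- diff(range(x))
  lower <- log(c(1e-4, 0.1 * span, 1e-4))
  upper <- log(c(1e4, 10 * span, 1e4))
  starts <- list(
    log(c(max(s2_hat, 1e-3), span / 3, max(s2_hat / 2, 1e-3))),
    c(lower[1], log(span / 3), log(s2_hat))   # static boundary start
  )
  old_seed <- if (exists(".Random.seed", .GlobalEnv)) {
    get(".Random.seed", .GlobalEnv)
  } else NULL
  set.seed(derive_seed(seed, "gpstarts"))
  while (length(starts) < n_restarts) {
    starts[[length(starts) + 1]] <- lower + runif(3) * (upper - lower)
  }
  if (!is.null(old_seed)) assign(".Random.seed", old_seed, .GlobalEnv)

  best <- NULL
  for (st in starts) {
    fit <- tryCatch(
      optim(st, fn = gp_loglik, gr = gp_loglik_grad, y = y, D2 = D2,
            method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(fnscale = -1, maxit = 200)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value > best$value)) best <- fit
  }
  if (is.null(best)) abort("GP optimisation failed for all starts")
  ll_dyn <- max(best$value, ll_static)  # nesting: static is a boundary case
  hp <- exp(best$par)
  dynamic_fit <- structure(list(
    model = "dynamic", log_marginal_likelihood = ll_dyn,
    hyperparams = c(sigma_f2 = hp[1], lengthscale = hp[2], sigma_n2 = hp[3]),
    k = 3L, n = n, bic = bic(3, n, ll_dyn)
  ), class = "gp_fit")

  list(dynamic = dynamic_fit, static = static_fit)
}

#' @export
print.gp_fit <- function(x, ...) {
  cat("<gp_fit> ", x$model, ": loglik = ", signif(x$log_marginal_likelihood, 6),
      ", BIC = ", signif(x$bic, 6), " (k = ", x$k, ", n = ", x$n, ")\n",
      sep = "")
  invisible(x)
}

#' Classify one profile from its two model fits
#'
#' Applies the two decision rules: BIC preference
#' (`bic_dynamic < bic_static`) and the stricter likelihood-ratio test,
#' `LR = 2 (loglik_dynamic - loglik_static)` (clipped at zero) referred to
#' the upper tail of chi-squared with one degree of freedom.
#'
#' @param fit_dynamic,fit_static `gp_fit` objects from [fit_gp_models()].
#' @param alpha Significance level for the LR test (default 0.05).
#' @return One-row tibble: `bic_dynamic`, `bic_static`, `lr`, `p_value`,
#'   `dynamic_by_bic`, `dynamic_by_lr`.
#' @export
classify_dynamics <- function(fit_dynamic, fit_static, alpha = 0.05) {
  stopifnot(inherits(fit_dynamic, "gp_fit"), inherits(fit_static, "gp_fit"))
  if (fit_dynamic$n != fit_static$n) {
    abort("fits have different observation counts; not from the same profile")
  }
  lr <- max(0, 2 * (fit_dynamic$log_marginal_likelihood -
                      fit_static$log_marginal_likelihood))
  p <- pchisq(lr, df = 1, lower.tail = FALSE)
  tibble(
    bic_dynamic = fit_dynamic$bic, bic_static = fit_static$bic,
    lr = lr, p_value = p,
    dynamic_by_bic = fit_dynamic$bic < fit_static$bic,
    dynamic_by_lr = p < alpha
  )
}

#' Call dynamic versus static for every feature in a profile table
#'
#' Normalises counts (CPM-like scaling, `log2(x + 1)`, per-feature
#' centring), fits the dynamic and static GP models to each feature and
#' applies both decision rules. This is the workhorse the accessibility,
#' interaction and expression time courses are all pushed through.
#'
#' @param profiles Long tibble with columns `feature_id`, `kind`, `time`,
#'   `replicate`, `count` (or a pre-normalised `value` column if
#'   `normalize = FALSE`).
#' @param alpha LR-test significance level (default 0.05).
#' @param time_transform Passed to [transform_times()].
#' @param normalize Apply [normalize_profiles()] first (default `TRUE`).
#' @param n_restarts,seed Optimiser start control, see [fit_gp_models()].
#' @return A `dynamics_calls` tibble, one row per feature: `feature_id`,
#'   `kind`, `bic_dynamic`, `bic_static`, `lr`, `p_value`,
#'   `dynamic_by_bic`, `dynamic_by_lr`.
#' @export
call_dynamics <- function(profiles, alpha = 0.05,
                          time_transform = "log2min",
                          normalize = TRUE, n_restarts = 5, seed = 1) {
  if (normalize) profiles <- normalize_profiles(profiles)
  if (!"value" %in% names(profiles)) {
    abort("profiles need a `value` column when normalize = FALSE")
  }
  calls <- profiles |>
    group_by(.data$feature_id, .data$kind) |>
    group_modify(function(d, g) {
      wide <- d |>
        arrange(.data$time, .data$replicate) |>
        pivot_wider(id_cols = "replicate", names_from = "time",
                    values_from = "value")
      times <- as.numeric(names(wide)[-1])
      vals <- as.matrix(wide[, -1])
      fits <- fit_gp_models(times, vals, time_transform = time_transform,
                            n_restarts = n_restarts, seed = seed)
      classify_dynamics(fits$dynamic, fits$static, alpha = alpha)
    }) |>
    ungroup()
  structure(calls, class = c("dynamics_calls", class(calls)),
            alpha = alpha, time_transform = time_transform)
}

#' @export
tidy.dynamics_calls <- function(x, ...) {
  class(x) <- setdiff(class(x), "dynamics_calls")
  as_tibble(x)
}

#' @export
glance.dynamics_calls <- function(x, ...) {
  tibble(
    n_features = nrow(x),
    n_dynamic_bic = sum(x$dynamic_by_bic),
    n_dynamic_lr = sum(x$dynamic_by_lr),
    frac_dynamic_bic = mean(x$dynamic_by_bic),
    frac_dynamic_lr = mean(x$dynamic_by_lr),
    alpha = attr(x, "alpha")
  )
}
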