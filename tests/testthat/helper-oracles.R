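# Independent oracles and small fixture builders shared across tests.

# Brute-force GP marginal-likelihood maximiser on a log-spaced grid over the
# same hyperparameter box as the package optimiser. Uses an
# eigendecomposition per lengthscale so the (signal, noise) sweep is vector
# arithmetic; independent of the package's Cholesky/quasi-Newton path.
grid_gp_loglik <- function(times, values, n_grid = 20) {
  if (is.vector(values)) values <- matrix(values, nrow = 1)
  x <- transform_times(times)
  reps <- nrow(values)
  xx <- rep(x, each = reps)
  y <- as.numeric(values)
  n <- length(y)
  span <- diff(range(x))
  sf2s <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  ells <- exp(seq(log(0.1 * span), log(10 * span), length.out = n_grid))
  sn2s <- exp(seq(log(1e-4), log(1e4), length.out = n_grid))
  best <- -Inf
  for (ell in ells) {
    C <- exp(-0.5 * outer(xx, xx, "-")^2 / ell^2)
    E <- eigen(C, symmetric = TRUE)
    z2 <- drop(crossprod(E$vectors, y))^2
    for (sf2 in sf2s) {
      lam0 <- sf2 * pmax(E$values, 0)
      for (sn2 in sn2s) {
        lam <- lam0 + sn2
        ll <- -0.5 * sum(z2 / lam) - 0.5 * sum(log(lam)) -
          n / 2 * log(2 * pi)
        if (ll > best) best <- ll
      }
    }
  }
  best
}

# Adjusted Rand index from the pair-counting formula; independent oracle for
# clustering recovery.
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  n2 <- choose2(sum(tab))
  expected <- sum_a * sum_b / n2
  maxi <- (sum_a + sum_b) / 2
  if (maxi == expected) return(1)
  (sum_ij - expected) / (maxi - expected)
}

# Long profile tibble from a matrix of per-time latent means (features x
# time points), replicated with Gaussian noise on the value scale.
profiles_from_means <- function(means, times, noise_sd = 0.1,
                                replicates = 2, kind = "peak",
                                prefix = "f") {
  stopifnot(ncol(means) == length(times))
  out <- list()
  for (i in seq_len(nrow(means))) {
    for (r in seq_len(replicates)) {
      out[[length(out) + 1]] <- tibble::tibble(
        feature_id = sprintf("%s_%03d", prefix, i), kind = kind,
        time = times, replicate = r,
        value = means[i, ] + rnorm(length(times), 0, noise_sd))
    }
  }
  dplyr::bind_rows(out)
}

# Cached small scaffold + simulation reused by several test files.
small_sim <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      sc <- simulate_genome(chrom_length = 5e6, n_fragments = 300,
                            n_genes = 25, n_peaks = 90, seed = 42)
      sim <- simulate_timecourses(sc, dyn_fraction = 0.4, seed = 42)
      cache <<- list(scaffold = sim$scaffold, profiles = sim$profiles,
                     truth = sim$truth)
    }
    cache
  }
})
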