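# Clustering of dynamic accessibility profiles into temporal archetypes
# with a Gaussian-process mixture model.

#' Pre-filter peaks before temporal clustering
#'
#' Retains accessibility peaks that (a) show at least an inclusive
#' improvement of the dynamic model over the static one,
#' `2 (loglik_dyn - loglik_static) > lr_threshold` (default 1 nat — more
#' inclusive than the chi-squared cut), and (b) lie outside every gene's
#' promoter window. The promoter window is strand-aware: for a `+` strand
#' gene it spans `[TSS - upstream, TSS + downstream)`, mirrored for `-`
#' strand genes.
#'
#' @param calls A `dynamics_calls` tibble (or any tibble with `feature_id`
#'   and `lr` columns).
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @param genes Tibble with `gene_id`, `chrom`, `tss`, `strand`.
#' @param lr_threshold Inclusive LR threshold in nats (default 1).
#' @param promoter_upstream,promoter_downstream Window half-widths in bp
#'   (defaults 1000 and 500).
#' @return Character vector of retained peak ids.
#' @export
prefilter_for_clustering <- function(calls, peaks, genes,
                                     lr_threshold = 1,
                                     promoter_upstream = 1000,
                                     promoter_downstream = 500) {
  if (nrow(genes) > 0 && any(!genes$strand %in% c("+", "-"))) {
    abort("gene strand must be '+' or '-' (promoter window is strand-dependent)")
  }
  keep_lr <- calls$feature_id[calls$lr > lr_threshold]
  cand <- peaks |> filter(.data$peak_id %in% keep_lr)
  if (nrow(cand) == 0 || nrow(genes) == 0) return(cand$peak_id)
  prom <- genes |>
    mutate(pstart = ifelse(.data$strand == "+",
                           .data$tss - promoter_upstream,
                           .data$tss - promoter_downstream),
           pend = ifelse(.data$strand == "+",
                         .data$tss + promoter_downstream,
                         .data$tss + promoter_upstream))
  hit <- cand |>
    inner_join(prom, by = "chrom", relationship = "many-to-many") |>
    filter(overlap_width(.data$start, .data$end, .data$pstart, .data$pend) > 0) |>
    distinct(.data$peak_id)
  setdiff(cand$peak_id, hit$peak_id)
}

#' Cluster temporal profiles with a Gaussian-process mixture model
#'
#' Replicate-averaged, normalised profiles are modelled as a K-component
#' mixture: component k has a latent mean function with a
#' squared-exponential GP prior on the transformed time grid, plus shared
#' isotropic noise. Fitting is by EM with maximum-a-posteriori updates of
#' the cluster mean functions; the penalised log-likelihood objective is
#' non-decreasing across iterations. Initialisation is k-means on the
#' profile vectors under the given seed.
#'
#' @param profiles Long tibble of counts (`feature_id`, `kind`, `time`,
#'   `replicate`, `count`), or of pre-normalised values if
#'   `normalize = FALSE`.
#' @param k Number of clusters (default 6, the number of broad temporal
#'   patterns seen in stimulated-T-cell accessibility data).
#' @param prior_lengthscale GP prior lengthscale on the transformed axis
#'   (default a third of the axis span).
#' @param time_transform Passed to [transform_times()].
#' @param normalize Apply [normalize_profiles()] + replicate averaging.
#' @param max_iter,tol EM stopping rule: relative objective change below
#'   `tol` (default 1e-6) or `max_iter` (default 500) iterations.
#' @param seed Integer seed for initialisation.
#' @return A `gp_mixture` object: list with `k`, `assignments` (named
#'   integer vector), `responsibilities` (features x k matrix, rows sum
#'   to 1), `cluster_means` (k x time grid matrix), `mixing` (proportions),
#'   `noise_var`, `times`, `objective` (per-iteration trace), `converged`,
#'   `final_objective`.
#' @export
cluster_profiles <- function(profiles, k = 6,
                             prior_lengthscale = NULL,
                             time_transform = "log2min",
                             normalize = TRUE,
                             max_iter = 500, tol = 1e-6, seed = 1) {
  if (normalize) {
    profiles <- normalize_profiles(profiles) |> average_replicates()
  }
  if (!"value" %in% names(profiles)) {
    abort("profiles need a `value` column when normalize = FALSE")
  }
  wide <- profiles |>
    select("feature_id", "time", "value") |>
    arrange(.data$feature_id, .data$time) |>
    pivot_wider(names_from = "time", values_from = "value") |>
    arrange(.data$feature_id)
  ids <- wide$feature_id
  Y <- as.matrix(wide[, -1])
  times <- as.numeric(colnames(Y))
  n <- nrow(Y); tt <- ncol(Y)
  if (k < 1) abort("k must be at least 1")
  if (k > n) abort("k cannot exceed the number of profiles")

  x <- transform_times(times, time_transform)
  span <- diff(range(x))
  if (is.null(prior_lengthscale)) prior_lengthscale <- span / 3
  Kprior <- var(as.numeric(Y)) *
    exp(-0.5 * outer(x, x, "-")^2 / prior_lengthscale^2) + diag(1e-8, tt)
  Kprior_inv <- solve(Kprior)

  set.seed(derive_seed(seed, "gpmix"))
  init <- if (k == 1) rep(1L, n) else {
    kmeans(Y, centers = k, nstart = 5, iter.max = 50)$cluster
  }
  M <- t(vapply(seq_len(k), function(j) colMeans(Y[init == j, , drop = FALSE]),
                numeric(tt)))
  pi_k <- as.numeric(table(factor(init, levels = seq_len(k)))) / n
  pi_k <- pmax(pi_k, 1e-8); pi_k <- pi_k / sum(pi_k)
  s2 <- max(mean((Y - M[init, , drop = FALSE])^2), 1e-6)

  penalty <- function(M) -0.5 * sum(vapply(seq_len(k), function(j)
    drop(M[j, ] %*% Kprior_inv %*% M[j, ]), numeric(1)))
  objective <- numeric(0)
  converged <- FALSE
  R <- matrix(1 / k, n, k)
  for (it in seq_len(max_iter)) {
    ## E-step
    logdens <- vapply(seq_len(k), function(j) {
      -0.5 * rowSums(sweep(Y, 2, M[j, ])^2) / s2 -
        tt / 2 * log(2 * pi * s2) + log(pi_k[j])
    }, numeric(n))
    logdens <- matrix(logdens, nrow = n)
    mx <- apply(logdens, 1, max)
    lse <- mx + log(rowSums(exp(logdens - mx)))
    R <- exp(logdens - lse)
    obj <- sum(lse) + penalty(M)
    objective <- c(objective, obj)
    if (it > 1 && abs(obj - objective[it - 1]) <=
        tol * (abs(objective[it - 1]) + 1e-12)) {
      converged <- TRUE
      break
    }
    ## M-step: MAP cluster means under the GP prior, then noise and weights
    Nk <- colSums(R)
    pi_k <- pmax(Nk / n, 1e-10); pi_k <- pi_k / sum(pi_k)
    for (j in seq_len(k)) {
      A <- Kprior_inv + diag(Nk[j] / s2, tt)
      b <- colSums(R[, j] * Y) / s2
      M[j, ] <- solve(A, b)
    }
    s2 <- max(sum(vapply(seq_len(k), function(j)
      sum(R[, j] * rowSums(sweep(Y, 2, M[j, ])^2)), numeric(1))) / (n * tt),
      1e-8)
  }
  assignments <- max.col(R, ties.method = "first")
  names(assignments) <- ids
  rownames(R) <- ids
  structure(list(
    k = k, assignments = assignments, responsibilities = R,
    cluster_means = M, mixing = pi_k, noise_var = s2, times = times,
    objective = objective, converged = converged,
    final_objective = objective[length(objective)]
  ), class = "gp_mixture")
}

#' @export
print.gp_mixture <- function(x, ...) {
  cat("<gp_mixture> k = ", x$k, ", ", length(x$assignments), " profiles, ",
      ifelse(x$converged, "converged", "not converged"), " after ",
      length(x$objective), " iterations (objective ",
      signif(x$final_objective, 6), ")\n", sep = "")
  cat("cluster sizes:", as.numeric(table(x$assignments)), "\n")
  invisible(x)
}

#' @export
tidy.gp_mixture <- function(x, ...) {
  tibble(feature_id = names(x$assignments),
         cluster = unname(x$assignments),
         max_responsibility = apply(x$responsibilities, 1, max))
}

#' @export
glance.gp_mixture <- function(x, ...) {
  tibble(k = x$k, n_profiles = length(x$assignments),
         converged = x$converged, iterations = length(x$objective),
         final_objective = x$final_objective, noise_var = x$noise_var)
}

#' Plot fitted cluster mean functions
#'
#' @param object A `gp_mixture`.
#' @param ... Unused.
#' @return A ggplot: one mean trajectory per cluster over the time grid.
#' @export
autoplot.gp_mixture <- function(object, ...) {
  df <- as_tibble(object$cluster_means, .name_repair = "minimal")
  names(df) <- as.character(object$times)
  df$cluster <- factor(seq_len(object$k))
  df <- pivot_longer(df, -"cluster", names_to = "time", values_to = "mean") |>
    mutate(time = as.numeric(.data$time))
  sizes <- table(object$assignments)
  df$label <- sprintf("cluster %s (n = %d)", df$cluster,
                      as.integer(sizes[as.character(df$cluster)]))
  ggplot(df, aes(x = log2(1 + .data$time), y = .data$mean,
                 colour = .data$label)) +
    geom_line() + geom_point(size = 1) +
    labs(x = "log2(1 + minutes)", y = "normalised signal (centred)",
         colour = NULL, title = "GP mixture cluster means") +
    theme_minimal()
}
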