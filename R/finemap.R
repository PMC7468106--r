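# Wakefield approximate Bayes factors and 99% credible SNP sets.

#' Wakefield approximate Bayes factor
#'
#' Closed-form evidence in favour of association for a SNP with estimated
#' log odds ratio `beta` and variance `V`, under a normal prior on the
#' allelic effect with variance `omega`:
#' `sqrt(V / (V + omega)) * exp(omega * beta^2 / (2 V (V + omega)))`.
#' Computed in log space so GWAS-scale Z values do not overflow.
#'
#' @param beta Estimated log odds ratio(s).
#' @param V Variance of the estimate (`se^2`); must be positive.
#' @param omega Prior variance of the allelic effect (default 0.04).
#' @param log Return the natural log of the Bayes factor.
#' @return Positive numeric vector (or its log).
#' @export
approx_bayes_factor <- function(beta, V, omega = 0.04, log = FALSE) {
  if (any(V <= 0)) abort("V must be positive")
  if (any(omega < 0)) abort("omega must be non-negative")
  q <- omega * beta^2 / (2 * V * (V + omega))
  if (log) {
    0.5 * (base::log(V) - base::log(V + omega)) + q
  } else {
    sqrt(V / (V + omega)) * exp(q)   # exact shrinkage factor when beta = 0
  }
}

#' Construct the credible SNP set for each locus
#'
#' Per locus: the posterior probability of causality of each SNP is its
#' approximate Bayes factor divided by the locus total; SNPs are ranked by
#' Bayes factor (ties broken by position then rsid) and included until the
#' cumulative posterior attains or exceeds `level`.
#'
#' @param stats Tibble with columns `rsid`, `beta`, and either `V` or `se`
#'   (`V = se^2` is derived at ingest); optional `locus_id`, `chrom`, `pos`.
#' @param level Credible level in (0, 1) (default 0.99).
#' @param omega Prior effect variance (default 0.04).
#' @return A `credible_sets` tibble, one row per SNP, grouped implicitly by
#'   `locus_id`, with `abf`, `posterior`, `cum_posterior`, `rank` and
#'   `in_set` appended; ordered by locus then rank.
#' @export
credible_set <- function(stats, level = 0.99, omega = 0.04) {
  if (nrow(stats) == 0) abort("empty locus: no SNPs supplied")
  if (level <= 0 || level >= 1) abort("level must lie in (0, 1)")
  if (!"V" %in% names(stats)) {
    if (!"se" %in% names(stats)) abort("stats need a `V` or `se` column")
    stats <- stats |> mutate(V = .data$se^2)
  }
  if (!"locus_id" %in% names(stats)) {
    stats <- stats |> mutate(locus_id = "locus_1")
  }
  if (!"pos" %in% names(stats)) stats <- stats |> mutate(pos = NA_integer_)
  out <- stats |>
    group_by(.data$locus_id) |>
    group_modify(function(d, g) {
      labf <- approx_bayes_factor(d$beta, d$V, omega, log = TRUE)
      post <- exp(labf - max(labf))
      post <- post / sum(post)
      d$abf <- exp(labf)
      d$posterior <- post
      d <- d[order(-labf, d$pos, d$rsid), ]
      d$rank <- seq_len(nrow(d))
      d$cum_posterior <- cumsum(d$posterior)
      # minimal prefix whose cumulative posterior attains the level
      cut <- which(d$cum_posterior >= level - 1e-12)[1]
      if (is.na(cut)) cut <- nrow(d)
      d$in_set <- d$rank <= cut
      d
    }) |>
    ungroup()
  structure(out, class = c("credible_sets", class(out)),
            level = level, omega = omega)
}

#' @export
tidy.credible_sets <- function(x, ...) {
  class(x) <- setdiff(class(x), "credible_sets")
  as_tibble(x)
}

#' @export
glance.credible_sets <- function(x, ...) {
  x |>
    as_tibble() |>
    group_by(.data$locus_id) |>
    summarise(n_snps = n(), set_size = sum(.data$in_set),
              top_snp = .data$rsid[.data$rank == 1],
              top_posterior = max(.data$posterior), .groups = "drop") |>
    mutate(level = attr(x, "level"), omega = attr(x, "omega"))
}

#' Plot per-locus posterior concentration
#'
#' @param object A `credible_sets` tibble.
#' @param ... Unused.
#' @return A ggplot of ranked cumulative posterior per locus, with the
#'   credible level marked.
#' @export
autoplot.credible_sets <- function(object, ...) {
  lvl <- attr(object, "level")
  ggplot(as_tibble(object),
         aes(x = .data$rank, y = .data$cum_posterior,
             colour = .data$locus_id)) +
    geom_step() +
    geom_hline(yintercept = lvl, linetype = "dashed") +
    labs(x = "SNP rank (by Bayes factor)", y = "cumulative posterior",
         colour = NULL,
         title = sprintf("Credible-set construction (level %.2f)", lvl)) +
    theme_minimal()
}
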