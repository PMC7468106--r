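# Higher-order chromatin stability metrics: TAD/compartment reciprocal
# overlap, compartment-score correlation decay with time separation, and a
# simplified stratum-adjusted correlation coefficient (SCC) for contact
# matrices.

#' Fraction of intervals with a reciprocal-overlap partner
#'
#' For each interval in `track_a`, looks for an interval in `track_b`
#' overlapping at least `min_frac` of both lengths (90% reciprocal by
#' default); returns the matched fraction of `track_a`. The measure is
#' deliberately asymmetric: the denominator is the interval count of the
#' first track.
#'
#' @param track_a,track_b Tibbles with `chrom`, `start`, `end`.
#' @param min_frac Reciprocal-overlap fraction in (0, 1\] (default 0.9).
#' @return Fraction in \[0, 1\].
#' @export
reciprocal_overlap_fraction <- function(track_a, track_b, min_frac = 0.9) {
  if (nrow(track_a) == 0) abort("track_a is empty")
  if (min_frac <= 0 || min_frac > 1) abort("min_frac must lie in (0, 1]")
  if (nrow(track_b) == 0) return(0)
  matched <- track_a |>
    mutate(.row = row_number(), len_a = .data$end - .data$start) |>
    inner_join(track_b |>
                 mutate(len_b = .data$end - .data$start) |>
                 rename(start_b = "start", end_b = "end"),
               by = "chrom", relationship = "many-to-many") |>
    mutate(ov = overlap_width(.data$start, .data$end,
                              .data$start_b, .data$end_b)) |>
    filter(.data$ov >= min_frac * .data$len_a,
           .data$ov >= min_frac * .data$len_b) |>
    distinct(.data$.row)
  nrow(matched) / nrow(track_a)
}

#' Reciprocal-overlap consistency across all time-point pairs
#'
#' @param tracks Tibble with `time`, `chrom`, `start`, `end` (e.g. the
#'   scaffold's `tads_by_time`).
#' @param min_frac Passed to [reciprocal_overlap_fraction()].
#' @return Tibble with `time_a`, `time_b`, `fraction` (fraction of the
#'   `time_a` track matched in the `time_b` track).
#' @export
consistency_by_time <- function(tracks, min_frac = 0.9) {
  times <- sort(unique(tracks$time))
  crossing(time_a = times, time_b = times) |>
    filter(.data$time_a != .data$time_b) |>
    mutate(fraction = map2_dbl(.data$time_a, .data$time_b, function(a, b) {
      reciprocal_overlap_fraction(tracks |> filter(.data$time == a),
                                  tracks |> filter(.data$time == b),
                                  min_frac)
    }))
}

#' Merge intervals across time points
#'
#' Single-linkage union of overlapping intervals pooled over all time
#' points; used to report merged TAD/compartment counts and mean sizes.
#'
#' @param tracks Tibble with `chrom`, `start`, `end` (any extra columns
#'   ignored).
#' @return Tibble of merged intervals with `chrom`, `start`, `end`.
#' @export
merge_intervals <- function(tracks) {
  tracks |>
    select("chrom", "start", "end") |>
    arrange(.data$chrom, .data$start, .data$end) |>
    group_by(.data$chrom) |>
    mutate(new_run = .data$start > lag(cummax(.data$end),
                                       default = -Inf),
           run = cumsum(.data$new_run)) |>
    group_by(.data$chrom, .data$run) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop") |>
    select("chrom", "start", "end")
}

#' Compartment-score correlation versus time separation
#'
#' Orients each sample's eigen-score vector so its correlation with the
#' first sample is non-negative (PCA sign is arbitrary), computes Pearson
#' correlation for every sample pair on the shared bin grid, and fits an
#' ordinary least-squares line of correlation against absolute time
#' separation.
#'
#' @param scores Tibble with `time`, `start` (bin), `score`; optional
#'   `chrom`.
#' @return A `compartment_trend` list: `pairs` tibble (`time_a`, `time_b`,
#'   `dt`, `r`), `slope`, `intercept`.
#' @export
compartment_corr_trend <- function(scores) {
  key_cols <- intersect(c("chrom", "start"), names(scores))
  wide <- scores |>
    select(all_of(key_cols), "time", "score") |>
    pivot_wider(names_from = "time", values_from = "score") |>
    select(-all_of(key_cols))
  wide <- wide[complete.cases(wide), , drop = FALSE]
  if (ncol(wide) < 2) abort("at least 2 samples/time points are required")
  if (nrow(wide) < 2) abort("fewer than 2 shared bins across samples")
  M <- as.matrix(wide)
  times <- as.numeric(colnames(M))
  # sign orientation against the first sample
  for (j in seq_len(ncol(M))[-1]) {
    if (cor(M[, 1], M[, j]) < 0) M[, j] <- -M[, j]
  }
  pairs <- crossing(a = seq_along(times), b = seq_along(times)) |>
    filter(.data$a < .data$b) |>
    mutate(time_a = times[.data$a], time_b = times[.data$b],
           dt = abs(.data$time_b - .data$time_a),
           r = map2_dbl(.data$a, .data$b,
                        function(i, j) cor(M[, i], M[, j]))) |>
    select("time_a", "time_b", "dt", "r")
  fit <- lm(r ~ dt, data = pairs)
  structure(list(pairs = pairs,
                 slope = unname(coef(fit)[2]),
                 intercept = unname(coef(fit)[1])),
            class = "compartment_trend")
}

#' @export
print.compartment_trend <- function(x, ...) {
  cat("<compartment_trend> ", nrow(x$pairs), " sample pairs; r ~ |dt|: ",
      "slope = ", signif(x$slope, 4), ", intercept = ",
      signif(x$intercept, 4), "\n", sep = "")
  invisible(x)
}

#' @export
glance.compartment_trend <- function(x, ...) {
  tibble(n_pairs = nrow(x$pairs), slope = x$slope, intercept = x$intercept,
         mean_r = mean(x$pairs$r))
}

#' @export
autoplot.compartment_trend <- function(object, ...) {
  ggplot(object$pairs, aes(x = .data$dt, y = .data$r)) +
    geom_point() +
    geom_abline(slope = object$slope, intercept = object$intercept,
                linetype = "dashed") +
    labs(x = "time separation (min)", y = "Pearson r of compartment scores",
         title = "Compartment correlation versus time separation") +
    theme_minimal()
}

#' Simplified stratum-adjusted correlation coefficient
#'
#' For each off-diagonal distance stratum `d = 1 .. max_dist_bins`, the
#' Pearson correlation `r_d` between the two matrices' entries at that
#' distance is computed; the SCC is the weighted mean of the `r_d` with
#' weights `N_d * sd_a,d * sd_b,d`. Zero-variance strata are skipped. This
#' is the distance-stratified reproducibility measure for contact maps,
#' without the 2D mean-filter smoothing step of the full method.
#'
#' @param matrix_a,matrix_b Square symmetric contact matrices of equal
#'   dimension.
#' @param max_dist_bins Largest stratum (default `nrow - 1`).
#' @return SCC value in \[-1, 1\] (NA if every stratum is degenerate).
#' @export
scc <- function(matrix_a, matrix_b, max_dist_bins = NULL) {
  if (!all(dim(matrix_a) == dim(matrix_b))) abort("matrix shapes differ")
  if (nrow(matrix_a) != ncol(matrix_a)) abort("matrices must be square")
  n <- nrow(matrix_a)
  if (is.null(max_dist_bins)) max_dist_bins <- n - 1
  max_dist_bins <- min(max_dist_bins, n - 1)
  num <- 0; den <- 0
  for (d in seq_len(max_dist_bins)) {
    i <- seq_len(n - d)
    a <- matrix_a[cbind(i, i + d)]
    b <- matrix_b[cbind(i, i + d)]
    if (length(a) < 2) next
    sda <- sd(a); sdb <- sd(b)
    if (sda == 0 || sdb == 0) next
    w <- length(a) * sda * sdb
    num <- num + w * cor(a, b)
    den <- den + w
  }
  if (den == 0) return(NA_real_)
  num / den
}
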