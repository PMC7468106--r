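# Shared helpers: time transform, count normalisation, interval arithmetic,
# rounding conventions used in reported percentages.

#' Default stimulation time grid
#'
#' Minutes after CD3/CD28 stimulation at which libraries were sampled:
#' 0, 20 min, 1 h, 2 h, 4 h and 24 h.
#'
#' @return Numeric vector of six time points, in minutes.
#' @export
default_times <- function() c(0, 20, 60, 120, 240, 1440)

#' Transform the time axis before Gaussian-process fitting
#'
#' The sampling grid is heavily right-skewed (the last gap spans 4 h to
#' 24 h), so the default transform is `log2(1 + minutes)`, which roughly
#' equalises the spacing. `"hours"` keeps the raw axis in hours.
#'
#' @param times Numeric vector of times in minutes.
#' @param method `"log2min"` (default) or `"hours"`.
#' @return Transformed numeric vector.
#' @export
transform_times <- function(times, method = c("log2min", "hours")) {
  method <- match.arg(method)
  switch(method,
    log2min = log2(1 + times),
    hours   = times / 60
  )
}

#' Round half away from zero
#'
#' Base R rounds half to even; reported percentages here use the
#' half-away-from-zero convention (e.g. 10.5 -> 11).
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_away <- function(x, digits = 0) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

#' Normalise time-course counts
#'
#' Library-size scaling to counts-per-million within each sample (a sample
#' is one `kind` x `replicate` x `time` combination, i.e. one sequencing
#' library), then `log2(x + 1)`, then mean-centring within each feature.
#' The CPM step makes downstream dynamic/static calls invariant to a global
#' rescaling of counts; centring matches the zero-mean Gaussian-process
#' models.
#'
#' @param profiles Long tibble with columns `feature_id`, `kind`, `time`,
#'   `replicate`, `count`.
#' @param center Mean-centre each feature's values (default `TRUE`).
#' @return The input with a `value` column appended.
#' @export
normalize_profiles <- function(profiles, center = TRUE) {
  stopifnot(all(c("feature_id", "kind", "time", "replicate", "count") %in%
                  names(profiles)))
  if (any(profiles$count < 0)) abort("counts must be non-negative")
  out <- profiles |>
    group_by(.data$kind, .data$replicate, .data$time) |>
    mutate(.lib = sum(.data$count)) |>
    ungroup() |>
    mutate(value = log2(.data$count / ifelse(.data$.lib > 0, .data$.lib, 1) *
                          1e6 + 1)) |>
    select(-".lib")
  if (center) {
    out <- out |>
      group_by(.data$feature_id) |>
      mutate(value = .data$value - mean(.data$value)) |>
      ungroup()
  }
  out
}

#' Average replicates of a normalised profile table
#'
#' Replicate-averaged series are used for the correlation stage; model
#' fitting uses all replicate observations jointly.
#'
#' @param profiles Long tibble with a `value` column (see
#'   [normalize_profiles()]).
#' @return Tibble with columns `feature_id`, `kind`, `time`, `value`.
#' @export
average_replicates <- function(profiles) {
  profiles |>
    group_by(.data$feature_id, .data$kind, .data$time) |>
    summarise(value = mean(.data$value), .groups = "drop") |>
    arrange(.data$feature_id, .data$time)
}

# Length of the intersection of [s1,e1) and [s2,e2); vectorised.
overlap_width <- function(s1, e1, s2, e2) {
  pmax(0, pmin(e1, e2) - pmax(s1, s2))
}

# Deterministic integer sub-seed derived from a user seed and a stage tag,
# kept below 2^31.
derive_seed <- function(seed, tag) {
  (as.integer(seed) + sum(utf8ToInt(tag)) * 1009L) %% 2147483587L
}
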