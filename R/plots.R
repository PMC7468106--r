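# Additional result plots (autoplot methods live next to their classes).

#' Plot LR statistics against BIC preference for a set of calls
#'
#' @param object A `dynamics_calls` tibble.
#' @param ... Unused.
#' @return A ggplot: per-feature LR statistic, coloured by the BIC call,
#'   with the chi-squared significance cut marked.
#' @export
autoplot.dynamics_calls <- function(object, ...) {
  alpha <- attr(object, "alpha") %||% 0.05
  cut <- stats::qchisq(1 - alpha, df = 1)
  df <- as_tibble(object) |>
    mutate(delta_bic = .data$bic_static - .data$bic_dynamic)
  ggplot(df, aes(x = .data$delta_bic, y = .data$lr,
                 colour = .data$dynamic_by_bic)) +
    geom_point(alpha = 0.6, size = 1) +
    geom_hline(yintercept = cut, linetype = "dashed") +
    facet_wrap(~kind) +
    labs(x = "BIC(static) - BIC(dynamic)", y = "LR statistic",
         colour = "dynamic by BIC",
         title = "Dynamic/static model selection") +
    theme_minimal()
}

#' Plot observed link correlations against the randomised background
#'
#' @param links Correlated link tibble (see [correlate_links()]).
#' @param enrichment Result of [background_enrichment()].
#' @return A ggplot: per-stratum density of the tested correlation with
#'   the background density overlaid in black.
#' @export
plot_link_enrichment <- function(links, enrichment) {
  col <- paste0("r_", enrichment$which)
  obs <- links |>
    filter(!.data$degenerate, !is.na(.data$stratum)) |>
    select("stratum", r = all_of(col))
  bg <- tibble(r = enrichment$null)
  ggplot(obs, aes(x = .data$r)) +
    geom_density(aes(colour = .data$stratum)) +
    geom_density(data = bg, colour = "black", linetype = "dashed") +
    labs(x = sprintf("Pearson r (%s)", enrichment$which), y = "density",
         colour = "distance stratum",
         title = "Link correlations versus randomised background") +
    theme_minimal()
}
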