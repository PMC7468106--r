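# GWAS variant prioritisation: LD expansion, peak overlap, gene assignment
# through correlated links, compartment trajectories and summary reporting.

#' Expand a lead SNP by linkage disequilibrium
#'
#' Returns every SNP whose r-squared with the lead reaches `r2_threshold`
#' (default 0.8, inclusive); the lead itself is always returned.
#'
#' @param ld Symmetric r-squared matrix with rsid dimnames.
#' @param lead rsid of the lead SNP.
#' @param r2_threshold Inclusion threshold (default 0.8).
#' @return Character vector of rsids.
#' @export
ld_expand <- function(ld, lead, r2_threshold = 0.8) {
  if (!lead %in% rownames(ld)) abort(sprintf("lead SNP %s not in LD panel", lead))
  rownames(ld)[ld[lead, ] >= r2_threshold | rownames(ld) == lead]
}

#' Overlap SNP positions with peak intervals
#'
#' Half-open convention: a SNP at `pos` overlaps a peak when
#' `start <= pos < end` on the same chromosome.
#'
#' @param snps Tibble with `rsid`, `chrom`, `pos`.
#' @param peaks Tibble with `peak_id`, `chrom`, `start`, `end`.
#' @return Tibble of (`rsid`, `pos`, `peak_id`) pairs.
#' @export
overlap_snps_peaks <- function(snps, peaks) {
  snps |>
    select("rsid", "chrom", "pos") |>
    inner_join(peaks |> select("peak_id", "chrom", "start", "end"),
               by = "chrom", relationship = "many-to-many") |>
    filter(.data$start <= .data$pos, .data$pos < .data$end) |>
    select("rsid", "pos", "peak_id")
}

#' Assign genes to SNP-bearing peaks through correlated links
#'
#' A hit is emitted for every (SNP, peak, gene) where the peak's link to
#' the gene has all three pairwise correlations at or above `r_threshold`
#' (signed by default; set `absolute = TRUE` to threshold on magnitude).
#'
#' @param pairs (`rsid`, `pos`, `peak_id`) tibble from
#'   [overlap_snps_peaks()].
#' @param links Correlated link tibble (see [correlate_links()]).
#' @param r_threshold Correlation threshold (default 0.5).
#' @param absolute Threshold on `abs(r)` instead of signed r.
#' @return Tibble of hits: `rsid`, `pos`, `peak_id`, `gene_id`,
#'   `interaction_id`, `distance`, `stratum`, the three correlations.
#' @export
assign_genes <- function(pairs, links, r_threshold = 0.5, absolute = FALSE) {
  f <- if (absolute) abs else identity
  good <- links |>
    filter(!.data$degenerate,
           f(.data$r_atac_chic) >= r_threshold,
           f(.data$r_atac_gene) >= r_threshold,
           f(.data$r_gene_chic) >= r_threshold)
  pairs |>
    inner_join(good, by = "peak_id", relationship = "many-to-many") |>
    select("rsid", "pos", "peak_id", "gene_id", "interaction_id",
           "distance", "stratum", "r_atac_chic", "r_atac_gene",
           "r_gene_chic")
}

#' Classify each SNP's A/B compartment trajectory
#'
#' Labels each SNP at each time point by the compartment interval
#' containing it, then classifies the trajectory: `consistent A`,
#' `consistent B`, `switching` (any label change over time) or
#' `unassigned` (never inside a compartment).
#'
#' @param snps Tibble with `rsid`, `chrom`, `pos`.
#' @param compartments Tibble with `time`, `chrom`, `start`, `end`,
#'   `label` (`"A"`/`"B"`).
#' @return List with `trajectories` (long tibble: `rsid`, `time`, `label`)
#'   and `classes` (tibble: `rsid`, `class`).
#' @export
compartment_membership <- function(snps, compartments) {
  times <- sort(unique(compartments$time))
  if (length(times) < 2) abort("compartment tracks must cover >= 2 time points")
  bad <- compartments |>
    group_by(.data$time, .data$chrom) |>
    arrange(.data$start, .by_group = TRUE) |>
    filter(lead(.data$start) < .data$end) |>
    ungroup()
  if (nrow(bad) > 0) {
    abort("overlapping compartment intervals within one time point")
  }
  traj <- crossing(snps |> select("rsid", "chrom", "pos"), time = times) |>
    left_join(compartments, by = c("chrom", "time"),
              relationship = "many-to-many") |>
    mutate(inside = !is.na(.data$start) & .data$start <= .data$pos &
             .data$pos < .data$end) |>
    group_by(.data$rsid, .data$time) |>
    summarise(label = if (any(.data$inside)) {
      .data$label[.data$inside][1]
    } else NA_character_, .groups = "drop")
  classes <- traj |>
    group_by(.data$rsid) |>
    summarise(class = {
      lab <- .data$label[!is.na(.data$label)]
      if (length(lab) == 0) "unassigned"
      else if (all(lab == "A")) "consistent A"
      else if (all(lab == "B")) "consistent B"
      else "switching"
    }, .groups = "drop")
  list(trajectories = traj, classes = classes)
}

#' Summary statistics of a prioritisation run
#'
#' Ratios are reported as percentages, `numerator / denominator * 100`,
#' rounded half away from zero to the requested precision; the mean number
#' of genes per peak is the distinct-gene count over the distinct-peak
#' count at one decimal.
#'
#' @param ratios Optional tibble with `name`, `numerator`, `denominator`
#'   and optional `digits` (default 0) columns.
#' @param hits Optional hit tibble (see [assign_genes()]); adds counts and
#'   `genes_per_peak`.
#' @param compartment_classes Optional classes tibble from
#'   [compartment_membership()]; adds per-class counts and percentages.
#' @return A named list report: `percentages` tibble, and `counts` /
#'   `genes_per_peak` / `compartments` when the inputs are given.
#' @export
summary_report <- function(ratios = NULL, hits = NULL,
                           compartment_classes = NULL) {
  report <- list()
  if (!is.null(ratios)) {
    if (!"digits" %in% names(ratios)) ratios$digits <- 0L
    if (any(ratios$denominator == 0)) {
      abort(sprintf("zero denominator in ratio '%s'",
                    ratios$name[ratios$denominator == 0][1]))
    }
    report$percentages <- ratios |>
      mutate(percent = round_half_away(
        .data$numerator / .data$denominator * 100, .data$digits),
        formatted = paste0(
          format(.data$percent, trim = TRUE, scientific = FALSE), "%"))
  }
  if (!is.null(hits)) {
    n_peaks <- n_distinct(hits$peak_id)
    n_genes <- n_distinct(hits$gene_id)
    report$counts <- tibble(
      n_snps = n_distinct(hits$rsid), n_peaks = n_peaks, n_genes = n_genes)
    if (n_peaks == 0) abort("zero denominator in ratio 'genes_per_peak'")
    report$genes_per_peak <- round_half_away(n_genes / n_peaks, 1)
  }
  if (!is.null(compartment_classes)) {
    tot <- nrow(compartment_classes)
    report$compartments <- compartment_classes |>
      count(.data$class) |>
      mutate(percent = round_half_away(.data$n / tot * 100, 0))
  }
  report
}
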