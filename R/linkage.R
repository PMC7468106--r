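# Peak-interaction-gene linkage through bait/otherEnd geometry, Pearson
# correlation of the connected time courses, distance stratification and
# enrichment against a randomised background.

link_strata <- c("<200 kb", "200-500 kb", "500 kb-1 Mb", "1-5 Mb")

assign_stratum <- function(distance) {
  cut(distance, breaks = c(0, 2e5, 5e5, 1e6, 5e6),
      labels = link_strata, right = FALSE)
}

#' Retention filters for interactions and genes
#'
#' Interactions are kept when at least one time point's confidence score
#' exceeds `score_threshold` (strict inequality). Genes are kept when the
#' total count across time points reaches `min_gene_total` in every
#' replicate. Bait-to-bait interactions (otherEnd fragment is itself a
#' bait) are registered twice, with the bait and otherEnd roles swapped.
#'
#' @param interactions Tibble with `interaction_id`, `bait_fragment_id`,
#'   `oe_fragment_id` and `score_t*` columns (one per time point).
#' @param gene_profiles Long tibble of gene counts (`feature_id`, `time`,
#'   `replicate`, `count`).
#' @param bait_fragments Integer vector of all bait fragment ids (used to
#'   recognise bait-to-bait records).
#' @param score_threshold Confidence-score cut (default 5).
#' @param min_gene_total Minimum per-replicate total count (default 10).
#' @return List with `interactions` (filtered, bait-to-bait duplicated with
#'   a `swapped` flag) and `gene_ids` (retained genes).
#' @export
filter_features <- function(interactions, gene_profiles,
                            bait_fragments = integer(),
                            score_threshold = 5,
                            min_gene_total = 10) {
  score_cols <- grep("^score_t", names(interactions), value = TRUE)
  if (length(score_cols) == 0) abort("interactions carry no score_t* columns")
  max_score <- do.call(pmax, interactions[score_cols])
  kept <- interactions |>
    mutate(swapped = FALSE) |>
    filter(max_score > score_threshold)
  b2b <- kept |>
    filter(.data$oe_fragment_id %in% bait_fragments)
  if (nrow(b2b) > 0) {
    swapped <- b2b |>
      mutate(tmp = .data$bait_fragment_id,
             bait_fragment_id = .data$oe_fragment_id,
             oe_fragment_id = .data$tmp, swapped = TRUE) |>
      select(-"tmp")
    kept <- bind_rows(kept, swapped)
  }

  gene_ids <- character(0)
  if (nrow(gene_profiles) > 0) {
    gene_ids <- gene_profiles |>
      group_by(.data$feature_id, .data$replicate) |>
      summarise(total = sum(.data$count), .groups = "drop") |>
      group_by(.data$feature_id) |>
      summarise(keep = all(.data$total >= min_gene_total), .groups = "drop") |>
      filter(.data$keep) |>
      pull("feature_id")
  }
  list(interactions = kept, gene_ids = gene_ids)
}

#' Build candidate peak-interaction-gene links
#'
#' One link is emitted for every peak lying wholly inside an otherEnd
#' fragment, for every retained interaction originating from that fragment,
#' for every gene on the interaction's bait (baits carrying several genes
#' expand to one link per gene). Distance is measured between the bait and
#' otherEnd fragment midpoints; links at 5 Mb or beyond are dropped when
#' strata are assigned later.
#'
#' @param peaks Tibble with `peak_id`, `start`, `end`, `fragment_id`.
#' @param interactions Filtered interaction tibble (see [filter_features()]).
#' @param genes Gene tibble with `gene_id`, `bait_fragment_id`; only genes
#'   in `gene_ids` (if given) are linked.
#' @param fragments Fragment tibble with `fragment_id`, `start`, `end`.
#' @param gene_ids Optional retained-gene filter.
#' @return `links` tibble: `peak_id`, `interaction_id`, `bait_fragment_id`,
#'   `oe_fragment_id`, `gene_id`, `distance`, `stratum` (correlations unset).
#' @export
build_links <- function(peaks, interactions, genes, fragments,
                        gene_ids = NULL) {
  if (!is.null(gene_ids)) genes <- genes |> filter(.data$gene_id %in% gene_ids)
  frag <- fragments |>
    mutate(mid = (.data$start + .data$end) / 2) |>
    select("fragment_id", "mid")
  orphan <- peaks |>
    filter(is.na(.data$fragment_id) |
             !.data$fragment_id %in% fragments$fragment_id)
  if (nrow(orphan) > 0) {
    warn(sprintf("%d peak(s) assigned to no fragment were skipped",
                 nrow(orphan)))
  }
  peaks |>
    filter(!.data$peak_id %in% orphan$peak_id) |>
    select("peak_id", "fragment_id") |>
    inner_join(interactions |>
                 select("interaction_id", "bait_fragment_id",
                        "oe_fragment_id"),
               by = c(fragment_id = "oe_fragment_id"),
               relationship = "many-to-many") |>
    rename(oe_fragment_id = "fragment_id") |>
    inner_join(genes |> select("gene_id", "bait_fragment_id"),
               by = "bait_fragment_id", relationship = "many-to-many") |>
    left_join(frag |> rename(bait_mid = "mid"),
              by = c(bait_fragment_id = "fragment_id")) |>
    left_join(frag |> rename(oe_mid = "mid"),
              by = c(oe_fragment_id = "fragment_id")) |>
    mutate(distance = abs(.data$bait_mid - .data$oe_mid),
           stratum = assign_stratum(.data$distance)) |>
    select("peak_id", "interaction_id", "bait_fragment_id",
           "oe_fragment_id", "gene_id", "distance", "stratum")
}

#' Correlate the three time courses of each link
#'
#' Computes Pearson correlations between the replicate-averaged, normalised
#' series of the link's peak and interaction (`r_atac_chic`), peak and gene
#' (`r_atac_gene`) and gene and interaction (`r_gene_chic`). Links beyond
#' 5 Mb are dropped; links touching a zero-variance series get `NA`
#' correlations and are flagged `degenerate`.
#'
#' @param links Link tibble from [build_links()].
#' @param profiles Long count tibble covering all referenced features.
#' @param normalize Apply [normalize_profiles()] + replicate averaging.
#' @return The links with `r_atac_chic`, `r_atac_gene`, `r_gene_chic` and
#'   `degenerate` appended.
#' @export
correlate_links <- function(links, profiles, normalize = TRUE) {
  if (normalize) profiles <- normalize_profiles(profiles)
  avg <- average_replicates(profiles)
  series <- avg |>
    arrange(.data$feature_id, .data$time) |>
    group_by(.data$feature_id) |>
    summarise(series = list(.data$value), .groups = "drop")
  lookup <- setNames(series$series, series$feature_id)
  missing <- setdiff(unique(c(links$peak_id, links$interaction_id,
                              links$gene_id)), names(lookup))
  if (length(missing) > 0) {
    abort(sprintf("profiles missing for %d linked feature(s), e.g. %s",
                  length(missing), missing[1]))
  }
  safe_cor <- function(a, b) {
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }
  links |>
    filter(!is.na(.data$stratum)) |>
    mutate(
      r_atac_chic = map2_dbl(.data$peak_id, .data$interaction_id,
                             function(p, i) safe_cor(lookup[[p]], lookup[[i]])),
      r_atac_gene = map2_dbl(.data$peak_id, .data$gene_id,
                             function(p, g) safe_cor(lookup[[p]], lookup[[g]])),
      r_gene_chic = map2_dbl(.data$gene_id, .data$interaction_id,
                             function(g, i) safe_cor(lookup[[g]], lookup[[i]])),
      degenerate = is.na(.data$r_atac_chic) | is.na(.data$r_atac_gene) |
        is.na(.data$r_gene_chic)
    )
}

#' Compare observed link correlations with a randomised background
#'
#' The null is built by drawing `n_draws` random (peak, interaction, gene)
#' triplets uniformly from the supplied profiles, with no genomic
#' restriction, and computing the same Pearson correlation. Each distance
#' stratum's observed correlations are then compared with the null by a
#' two-sided Wilcoxon rank-sum test.
#'
#' @param links Correlated link tibble (see [correlate_links()]).
#' @param profiles Long count tibble (all peaks, interactions, genes).
#' @param which Which correlation to test: `"atac_chic"`, `"atac_gene"` or
#'   `"gene_chic"`.
#' @param n_draws Null sample size (default `max(10000, nrow(links))`).
#' @param seed Integer seed.
#' @param normalize Apply [normalize_profiles()] + replicate averaging.
#' @return List with `null` (numeric vector of background correlations) and
#'   `strata`, a tibble per stratum: `stratum`, `n`, `median_r`,
#'   `median_null`, `p_value` (NA when fewer than 2 observed values).
#' @export
background_enrichment <- function(links, profiles,
                                  which = c("atac_gene", "atac_chic",
                                            "gene_chic"),
                                  n_draws = NULL, seed = 1,
                                  normalize = TRUE) {
  which <- match.arg(which)
  if (!is.null(n_draws) && n_draws < 1) abort("n_draws must be at least 1")
  if (is.null(n_draws)) n_draws <- max(10000, nrow(links))
  if (normalize) profiles <- normalize_profiles(profiles)
  avg <- average_replicates(profiles)
  mats <- avg |>
    arrange(.data$feature_id, .data$time) |>
    group_by(.data$kind, .data$feature_id) |>
    summarise(series = list(.data$value), .groups = "drop")
  kinds <- strsplit(sub("atac", "peak", sub("chic", "interaction", which)),
                    "_")[[1]]
  pool_a <- mats |> filter(.data$kind == kinds[1]) |> pull("series")
  pool_b <- mats |> filter(.data$kind == kinds[2]) |> pull("series")
  if (length(pool_a) == 0 || length(pool_b) == 0) {
    abort("profiles lack one of the feature kinds needed for the null")
  }
  set.seed(derive_seed(seed, "background"))
  ia <- sample.int(length(pool_a), n_draws, replace = TRUE)
  ib <- sample.int(length(pool_b), n_draws, replace = TRUE)
  null_r <- vapply(seq_len(n_draws), function(i) {
    a <- pool_a[[ia[i]]]; b <- pool_b[[ib[i]]]
    if (sd(a) == 0 || sd(b) == 0) NA_real_ else cor(a, b)
  }, numeric(1))
  null_r <- null_r[!is.na(null_r)]

  col <- paste0("r_", which)
  obs <- links |>
    filter(!.data$degenerate) |>
    select("stratum", r = all_of(col))
  strata_tbl <- list_rbind(lapply(link_strata, function(s) {
    r <- obs$r[obs$stratum == s]
    p <- if (length(r) >= 2) {
      suppressWarnings(wilcox.test(r, null_r)$p.value)
    } else NA_real_
    tibble(stratum = s, n = length(r),
           median_r = if (length(r)) median(r) else NA_real_,
           median_null = median(null_r), p_value = p)
  }))
  list(null = null_r, strata = strata_tbl, which = which)
}

#' Log2 span of a time-course series
#'
#' `log2((max + c) / (min + c))` across time points, on the
#' replicate-averaged count scale with pseudocount `c` (default 1). Used to
#' compare the magnitude of change between accessibility, interaction and
#' expression series.
#'
#' @param series Numeric vector (one value per time point, counts).
#' @param pseudocount Added to numerator and denominator (default 1).
#' @return Scalar log2 fold change (0 for a constant series).
#' @export
log2_span <- function(series, pseudocount = 1) {
  if (length(series) == 0) abort("series is empty")
  log2((max(series) + pseudocount) / (min(series) + pseudocount))
}
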