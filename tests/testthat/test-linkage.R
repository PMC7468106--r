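# fixture: a 5-fragment chromosome with one peak, two baits and hand-laid
# interactions, small enough to reason through by eye
linkage_fixture <- function() {
  fragments <- tibble::tibble(
    fragment_id = 1:5, chrom = "chr1",
    start = c(0, 1e5, 2e5, 3e5, 4e5), end = c(1e5, 2e5, 3e5, 4e5, 5e5))
  genes <- tibble::tibble(
    gene_id = c("gA", "gB", "gC"), chrom = "chr1",
    tss = c(150000, 350000, 360000), strand = c("+", "-", "+"),
    bait_fragment_id = c(2L, 4L, 4L))  # bait 4 carries two genes
  peaks <- tibble::tibble(
    peak_id = "pk1", chrom = "chr1", start = 10000, end = 10400,
    fragment_id = 1L)
  interactions <- tibble::tibble(
    interaction_id = c("i1", "i2", "i3"),
    bait_fragment_id = c(2L, 4L, 2L),
    oe_fragment_id = c(1L, 1L, 4L),   # i3 is bait-to-bait
    score_t0 = c(0, 0, 0), score_t1 = c(0, 0, 0), score_t2 = c(0, 6, 0),
    score_t3 = c(5.1, 0, 0), score_t4 = c(0, 0, 7), score_t5 = c(0, 0, 0))
  list(fragments = fragments, genes = genes, peaks = peaks,
       interactions = interactions)
}

test_that("retention filters follow the printed inequalities", {
  fx <- linkage_fixture()
  gene_prof <- tidyr::crossing(feature_id = c("gA", "gB"),
                               time = default_times(),
                               replicate = 1:2) |>
    dplyr::mutate(kind = "gene",
                  count = ifelse(feature_id == "gA" & replicate == 1,
                                 1.5, 20))
  # gA totals: 9 in replicate 1, 120 in replicate 2 -> removed (every
  # replicate must reach the minimum)
  filt <- filter_features(fx$interactions, gene_prof,
                          bait_fragments = c(2L, 4L))
  expect_setequal(filt$gene_ids, "gB")
  # scores (0,0,0,5.1,0,0) with threshold 5: retained (strictly greater)
  expect_true("i1" %in% filt$interactions$interaction_id)
  # a score never exceeding 5 is dropped
  ints2 <- fx$interactions
  ints2$score_t3[1] <- 5.0
  filt2 <- filter_features(ints2, gene_prof, bait_fragments = c(2L, 4L))
  expect_false("i1" %in% filt2$interactions$interaction_id)
  # bait-to-bait registered as two directed records
  i3 <- dplyr::filter(filt$interactions, interaction_id == "i3")
  expect_equal(nrow(i3), 2)
  expect_setequal(i3$bait_fragment_id, c(2L, 4L))
  expect_setequal(i3$oe_fragment_id, c(4L, 2L))
  expect_error(filter_features(dplyr::select(fx$interactions,
                                             -dplyr::starts_with("score")),
                               gene_prof), "score")
})

test_that("links expand over interactions and bait genes", {
  fx <- linkage_fixture()
  links <- build_links(fx$peaks, fx$interactions, fx$genes, fx$fragments)
  # pk1 in fragment 1: i1 to bait 2 (gA) and i2 to bait 4 (gB, gC)
  expect_equal(sum(links$interaction_id == "i1"), 1)
  expect_equal(sum(links$interaction_id == "i2"), 2)  # two genes on bait 4
  expect_setequal(links$gene_id[links$interaction_id == "i2"], c("gB", "gC"))
  # distances are fragment-midpoint separations
  expect_equal(unique(links$distance[links$interaction_id == "i1"]), 1e5)
  expect_equal(unique(links$distance[links$interaction_id == "i2"]), 3e5)
  expect_equal(as.character(links$stratum[links$interaction_id == "i1"][1]),
               "<200 kb")
  expect_equal(as.character(links$stratum[links$interaction_id == "i2"][1]),
               "200-500 kb")
  # a peak in a fragment with no interactions yields nothing
  lonely <- dplyr::mutate(fx$peaks, fragment_id = 3L, peak_id = "pk_none")
  expect_equal(nrow(build_links(lonely, fx$interactions, fx$genes,
                                fx$fragments)), 0)
  # a peak assigned to no fragment is skipped with a warning
  orphan <- dplyr::bind_rows(fx$peaks,
                             dplyr::mutate(fx$peaks, peak_id = "pk_orphan",
                                           fragment_id = NA_integer_))
  expect_warning(build_links(orphan, fx$interactions, fx$genes,
                             fx$fragments), "skipped")
})

test_that("strata are half-open and links at 5 Mb or beyond are dropped", {
  sim <- small_sim()
  sc <- sim$scaffold
  filt <- filter_features(sc$interactions,
                          dplyr::filter(sim$profiles, kind == "gene"),
                          bait_fragments = unique(sc$genes$bait_fragment_id))
  links <- build_links(sc$peaks, filt$interactions, sc$genes, sc$fragments,
                       gene_ids = filt$gene_ids)
  corr <- correlate_links(links, sim$profiles)
  expect_true(all(!is.na(corr$stratum)))
  expect_true(all(corr$distance < 5e6))
  br <- list("<200 kb" = c(0, 2e5), "200-500 kb" = c(2e5, 5e5),
             "500 kb-1 Mb" = c(5e5, 1e6), "1-5 Mb" = c(1e6, 5e6))
  for (s in names(br)) {
    d <- corr$distance[corr$stratum == s]
    if (length(d)) expect_true(all(d >= br[[s]][1] & d < br[[s]][2]),
                               label = s)
  }
  # every link's peak lies wholly inside its otherEnd fragment
  pk <- sc$peaks[match(corr$peak_id, sc$peaks$peak_id), ]
  fr <- sc$fragments[match(corr$oe_fragment_id, sc$fragments$fragment_id), ]
  expect_true(all(pk$start >= fr$start & pk$end <= fr$end))
  expect_true(all(corr$r_atac_gene >= -1 & corr$r_atac_gene <= 1,
                  na.rm = TRUE))
})

test_that("perfectly shared and mirrored series give r = 1 and r = -1", {
  times <- default_times()
  vals <- c(-1, -0.5, 0, 0.5, 1, 1.5)
  prof <- dplyr::bind_rows(
    tibble::tibble(feature_id = "pk", kind = "peak", time = times,
                   replicate = 1L, value = vals),
    tibble::tibble(feature_id = "int", kind = "interaction", time = times,
                   replicate = 1L, value = vals * 2),
    tibble::tibble(feature_id = "gPos", kind = "gene", time = times,
                   replicate = 1L, value = vals + 0.3),
    tibble::tibble(feature_id = "gNeg", kind = "gene", time = times,
                   replicate = 1L, value = -vals),
    tibble::tibble(feature_id = "gFlat", kind = "gene", time = times,
                   replicate = 1L, value = rep(1, 6)))
  links <- tibble::tibble(
    peak_id = "pk", interaction_id = "int",
    bait_fragment_id = 1L, oe_fragment_id = 2L,
    gene_id = c("gPos", "gNeg", "gFlat"),
    distance = 150000, stratum = factor("<200 kb",
                                        levels = c("<200 kb", "200-500 kb",
                                                   "500 kb-1 Mb", "1-5 Mb")))
  out <- correlate_links(links, prof, normalize = FALSE)
  expect_equal(out$r_atac_gene[out$gene_id == "gPos"], 1.0)
  expect_equal(out$r_atac_gene[out$gene_id == "gNeg"], -1.0)
  expect_true(out$degenerate[out$gene_id == "gFlat"])
  expect_false(any(out$degenerate[out$gene_id != "gFlat"]))
  expect_equal(out$r_atac_chic[1], 1.0)
})

test_that("background nulls are calibrated and exchangeable across seeds", {
  sim <- small_sim()
  sc <- sim$scaffold
  filt <- filter_features(sc$interactions,
                          dplyr::filter(sim$profiles, kind == "gene"),
                          bait_fragments = unique(sc$genes$bait_fragment_id))
  links <- build_links(sc$peaks, filt$interactions, sc$genes, sc$fragments,
                       gene_ids = filt$gene_ids) |>
    correlate_links(sim$profiles)
  expect_error(background_enrichment(links, sim$profiles, n_draws = 0),
               "n_draws")
  e1 <- background_enrichment(links, sim$profiles, n_draws = 400, seed = 5)
  e2 <- background_enrichment(links, sim$profiles, n_draws = 400, seed = 6)
  # two seeds' nulls are draws from the same distribution
  ks <- suppressWarnings(stats::ks.test(e1$null, e2$null))
  expect_gt(ks$p.value, 1e-4)
  # observed values resampled from the null itself are not flagged
  fake <- links
  set.seed(5)
  idx <- sample(length(e1$null), nrow(fake), replace = TRUE)
  fake$r_atac_gene <- e1$null[idx]
  fake$degenerate <- FALSE
  cal <- background_enrichment(fake, sim$profiles, n_draws = 400, seed = 9)
  big <- dplyr::filter(cal$strata, n >= 20)
  expect_true(all(big$p_value > 0.01, na.rm = TRUE))
})

test_that("log2_span follows its closed form", {
  expect_equal(log2_span(rep(7, 6)), 0)
  expect_equal(log2_span(c(100, 800)), log2(801 / 101))
  expect_equal(log2_span(rep(0, 6)), 0)
  expect_error(log2_span(numeric(0)), "empty")
  # min >> pseudocount: span of an 8-fold change is close to 3
  expect_equal(log2_span(c(1000, 8000)), 3, tolerance = 0.01)
})
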