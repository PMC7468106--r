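test_that("LD expansion applies the r-squared threshold inclusively", {
  rs <- c("lead", "tight", "edge", "loose")
  ld <- matrix(c(1, 0.9, 0.8, 0.79,
                 0.9, 1, 0.7, 0.5,
                 0.8, 0.7, 1, 0.4,
                 0.79, 0.5, 0.4, 1), 4, 4, dimnames = list(rs, rs))
  got <- ld_expand(ld, "lead")
  expect_setequal(got, c("lead", "tight", "edge"))   # 0.8 in, 0.79 out
  expect_true("lead" %in% ld_expand(ld, "lead", r2_threshold = 1.1))
  expect_error(ld_expand(ld, "rs_missing"), "not in")
  # idempotent under single-lead semantics
  expect_setequal(ld_expand(ld, "lead"), got)
})

test_that("SNP-peak overlap uses the half-open convention", {
  peaks <- tibble::tibble(peak_id = c("pkA", "pkB"), chrom = c("chr1", "chr2"),
                          start = c(100L, 500L), end = c(200L, 600L))
  snps <- tibble::tibble(
    rsid = c("at_start", "at_end", "inside", "between", "wrong_chrom"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr3"),
    pos = c(100L, 200L, 150L, 300L, 150L))
  pairs <- overlap_snps_peaks(snps, peaks)
  expect_setequal(pairs$rsid, c("at_start", "inside"))
  expect_true(all(pairs$peak_id == "pkA"))
})

test_that("gene assignment requires all three correlations to clear the cut", {
  links <- tibble::tibble(
    peak_id = "pk", interaction_id = c("i1", "i2", "i3"),
    bait_fragment_id = 1L, oe_fragment_id = 2L,
    gene_id = c("g1", "g2", "g3"), distance = 1e5,
    stratum = factor("<200 kb"),
    r_atac_chic = c(0.9, 0.9, -0.8), r_atac_gene = c(0.8, 0.4, -0.9),
    r_gene_chic = c(0.7, 0.7, -0.7), degenerate = FALSE)
  pairs <- tibble::tibble(rsid = "rs1", pos = 150L, peak_id = "pk")
  hits <- assign_genes(pairs, links)
  expect_equal(hits$gene_id, "g1")             # (0.9, 0.4, 0.7) fails signed
  hits_abs <- assign_genes(pairs, links, absolute = TRUE)
  expect_setequal(hits_abs$gene_id, c("g1", "g3"))
  # two genes passing for one peak yield two hits
  links2 <- dplyr::mutate(links, r_atac_gene = 0.8)
  expect_equal(nrow(assign_genes(pairs, links2)), 2)
})

test_that("compartment trajectories classify consistent and switching SNPs", {
  comp <- dplyr::bind_rows(
    tibble::tibble(time = 20, chrom = "chr1",
                   start = c(0, 1000), end = c(1000, 2000),
                   label = c("A", "B")),
    tibble::tibble(time = 240, chrom = "chr1",
                   start = c(0, 1000), end = c(1000, 2000),
                   label = c("A", "A")))
  snps <- tibble::tibble(rsid = c("stayA", "flip", "outside"),
                         chrom = "chr1", pos = c(500L, 1500L, 5000L))
  cm <- compartment_membership(snps, comp)
  cls <- setNames(cm$classes$class, cm$classes$rsid)
  expect_equal(unname(cls["stayA"]), "consistent A")
  expect_equal(unname(cls["flip"]), "switching")   # B at 20 min, A at 4 h
  expect_equal(unname(cls["outside"]), "unassigned")
  expect_equal(nrow(cm$trajectories), 3 * 2)
  # overlapping intervals at one time point are a track error
  bad <- dplyr::bind_rows(comp,
                          tibble::tibble(time = 20, chrom = "chr1",
                                         start = 500, end = 1500,
                                         label = "A"))
  expect_error(compartment_membership(snps, bad), "overlapping")
  expect_error(compartment_membership(snps, dplyr::filter(comp, time == 20)),
               "2 time points")
})

test_that("reported ratios reproduce printed percentage conventions", {
  rep1 <- summary_report(ratios = tibble::tibble(
    name = c("chic_dynamic", "atac_dynamic", "zero"),
    numerator = c(63843, 7852, 0),
    denominator = c(271398, 74583, 100)))
  pct <- setNames(rep1$percentages$formatted, rep1$percentages$name)
  expect_equal(unname(pct["chic_dynamic"]), "24%")
  expect_equal(unname(pct["atac_dynamic"]), "11%")   # 10.53 rounds half away
  expect_equal(unname(pct["zero"]), "0%")
  one_dec <- summary_report(ratios = tibble::tibble(
    name = "stringent", numerator = 20224, denominator = 271398,
    digits = 1))
  expect_equal(one_dec$percentages$percent, 7.5)
  expect_error(summary_report(ratios = tibble::tibble(
    name = "bad", numerator = 1, denominator = 0)), "bad")
  # genes per peak at one decimal: 168 genes across 67 peaks -> 2.5
  hits <- tidyr::crossing(peak_id = sprintf("pk%02d", 1:67),
                          gene_id = sprintf("g%03d", 1:168)) |>
    dplyr::mutate(rsid = "rs1")
  rep2 <- summary_report(hits = hits)
  expect_equal(rep2$genes_per_peak, 2.5)
  expect_equal(rep2$counts$n_peaks, 67)
  expect_equal(rep2$counts$n_genes, 168)
})

test_that("rounding is half away from zero at every printed precision", {
  expect_equal(round_half_away(10.53), 11)
  expect_equal(round_half_away(0.5), 1)
  expect_equal(round_half_away(1.5), 2)
  expect_equal(round_half_away(2.5), 3)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(2.45, 1), 2.5)
  expect_equal(round_half_away(2.44, 1), 2.4)
})

test_that("hits are a subset of credible SNPs inside peaks", {
  res <- run_pipeline(pipeline_config(
    outdir = file.path(tempdir(), "pl_prio"), seed = 3,
    n_fragments = 250, n_genes = 20, n_peaks = 80, dyn_fraction = 0.4))
  if (nrow(res$hits) > 0) {
    cred <- dplyr::filter(tidy(res$credible), in_set)
    expect_true(all(res$hits$rsid %in% cred$rsid))
    pk <- res$scaffold$peaks
    m <- pk[match(res$hits$peak_id, pk$peak_id), ]
    expect_true(all(m$start <= res$hits$pos & res$hits$pos < m$end))
  }
  expect_true(is.list(res$report))
})
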