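test_that("scaffold satisfies its structural invariants", {
  sc <- simulate_genome(chrom_length = 1e7, n_fragments = 2000,
                        n_genes = 50, n_peaks = 300, seed = 1)
  # fragments tile the chromosome without overlap
  fr <- dplyr::arrange(sc$fragments, start)
  expect_equal(fr$start[1], 0)
  expect_equal(fr$end[nrow(fr)], sc$chrom_length)
  expect_true(all(fr$start[-1] == fr$end[-nrow(fr)]))
  expect_true(all(fr$end > fr$start))
  # counts forced by config
  expect_equal(nrow(sc$genes), 50)
  expect_equal(nrow(sc$peaks), 300)
  expect_equal(length(unique(sc$genes$bait_fragment_id)) <= 50, TRUE)
  # every peak wholly inside exactly its recorded fragment
  host <- sc$fragments[match(sc$peaks$fragment_id, sc$fragments$fragment_id), ]
  expect_true(all(sc$peaks$start >= host$start & sc$peaks$end <= host$end))
  # every gene maps to a real fragment containing its TSS
  bait <- sc$fragments[match(sc$genes$bait_fragment_id,
                             sc$fragments$fragment_id), ]
  expect_true(all(sc$genes$tss >= bait$start & sc$genes$tss < bait$end))
  # LD: symmetric, unit diagonal, entries in [0,1], PSD within tolerance
  expect_equal(sc$ld, t(sc$ld))
  expect_equal(unname(diag(sc$ld)), rep(1, nrow(sc$ld)))
  expect_true(all(sc$ld >= 0 & sc$ld <= 1))
  expect_gte(min(eigen(sc$ld, symmetric = TRUE, only.values = TRUE)$values),
             -1e-8)
})

test_that("degenerate configs and parameter errors are handled", {
  sc0 <- simulate_genome(n_fragments = 50, n_genes = 5, n_peaks = 0, seed = 2)
  expect_equal(nrow(sc0$peaks), 0)
  expect_error(simulate_genome(chrom_length = 0), "positive")
  expect_error(simulate_genome(n_peaks = -1), "non-negative")
  expect_error(simulate_timecourses(small_sim()$scaffold, replicates = 0),
               "replicates")
  expect_error(simulate_timecourses(small_sim()$scaffold, dyn_fraction = 2),
               "dyn_fraction")
})

test_that("same config and seed give a byte-identical serialised bundle", {
  d1 <- file.path(tempdir(), "sc_a"); d2 <- file.path(tempdir(), "sc_b")
  write_scaffold(simulate_genome(n_fragments = 120, n_genes = 8,
                                 n_peaks = 30, seed = 9), d1)
  write_scaffold(simulate_genome(n_fragments = 120, n_genes = 8,
                                 n_peaks = 30, seed = 9), d2)
  f1 <- list.files(d1); f2 <- list.files(d2)
  expect_setequal(f1, f2)
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  }
})

test_that("time-course generator honours truth labels and determinism", {
  sc <- small_sim()$scaffold
  s0 <- simulate_timecourses(sc, dyn_fraction = 0, seed = 5)
  expect_true(all(!s0$truth$dynamic))
  # static features have flat latent means: replicate/time means stay close
  s1a <- simulate_timecourses(sc, dyn_fraction = 0.5, seed = 6)
  s1b <- simulate_timecourses(sc, dyn_fraction = 0.5, seed = 6)
  expect_identical(s1a$profiles, s1b$profiles)
  expect_identical(s1a$truth, s1b$truth)
  # truth covers every generated profile
  expect_setequal(unique(s1a$profiles$feature_id), s1a$truth$feature_id)
  # coupled triplet members share dynamics: every true-link member dynamic
  tl <- sc$truth$true_links
  if (nrow(tl) > 0) {
    members <- unique(c(tl$peak_id, tl$interaction_id, tl$gene_id))
    lab <- s1a$truth$dynamic[match(members, s1a$truth$feature_id)]
    expect_true(all(lab))
  }
})

test_that("increasing dispersion at fixed signal cannot raise recovery", {
  sc <- simulate_genome(chrom_length = 4e6, n_fragments = 240, n_genes = 18,
                        n_peaks = 70, seed = 31)
  recov <- vapply(c(0.05, 0.5, 3), function(disp) {
    sim <- simulate_timecourses(sc, dyn_fraction = 1, dispersion = disp,
                                seed = 31)
    calls <- call_dynamics(sim$profiles, seed = 1)
    mean(calls$dynamic_by_lr)
  }, numeric(1))
  expect_true(all(diff(recov) <= 0.02))  # non-increasing up to MC noise
  expect_gt(recov[1], recov[3])
})

test_that("GWAS locus generator matches the single-causal-variant model", {
  g <- simulate_gwas_locus(n_snps = 40, beta = 0.25, se = 0.05, seed = 4)
  expect_equal(nrow(g$stats), 40)
  expect_true(g$causal_snp %in% g$stats$rsid)
  # expected attenuation: beta_j ~ r2_j * beta within sampling noise
  r2 <- g$ld[, g$causal_snp]
  resid <- g$stats$beta - r2[g$stats$rsid] * 0.25
  expect_lt(max(abs(resid)), 5 * 0.05)
  # single-SNP locus: credible set is that SNP with posterior 1
  g1 <- simulate_gwas_locus(n_snps = 1, seed = 4)
  cs <- credible_set(g1$stats)
  expect_equal(cs$posterior, 1)
  expect_true(cs$in_set)
  expect_error(simulate_gwas_locus(n_snps = 0, seed = 1), "n_snps")
  expect_error(simulate_gwas_locus(n_snps = 5, se = 0, seed = 1), "se")
})

test_that("contact matrices are symmetric and decorrelate with separation", {
  mats <- simulate_contact_matrices(n_bins = 60, seed = 2)
  expect_length(mats, 6)
  for (m in mats) expect_equal(m, t(m))
  s_near <- scc(mats[[2]], mats[[3]])
  s_far <- scc(mats[[2]], mats[[6]])
  expect_gt(s_near, s_far)
})
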