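# Synthetic genome scaffold and time-course generator.
#
# The generator emulates the structure of the stimulated CD4+ T-cell study
# design at toy scale: one chromosome tiled by restriction fragments, gene
# promoters on bait fragments, ATAC peaks inside fragments, promoter-capture
# interactions between bait and otherEnd fragments, per-time TAD and A/B
# compartment tracks, and a GWAS locus with one causal variant and LD decay.
# Ground-truth labels (dynamic/static, true links, causal SNP) ride along so
# every downstream stage can be scored.

#' Simulate a toy genome scaffold
#'
#' Builds a `scaffold_bundle` for a single synthetic chromosome: a
#' non-overlapping fragment tiling (restriction-fragment surrogate), genes
#' with TSS/strand mapped to bait fragments, peaks placed wholly inside
#' fragments, capture interactions from baits to otherEnd fragments with
#' CHiCAGO-like per-time scores, per-time TAD and A/B compartment tracks,
#' and a SNP panel with an exponential-decay LD matrix.
#'
#' A fraction of peaks is deliberately placed inside otherEnd fragments of
#' generated interactions so that peak-interaction-gene triplets exist; the
#' resulting candidate triplets are recorded in `truth$true_links`.
#'
#' @param chrom_length Chromosome length in bp (default 10 Mb).
#' @param n_fragments Number of restriction fragments tiling the chromosome.
#' @param n_genes Number of genes (each mapped to the bait fragment holding
#'   its TSS).
#' @param n_peaks Number of accessibility peaks.
#' @param seed Integer seed; the bundle is a deterministic function of the
#'   arguments.
#' @param times Time grid in minutes (default [default_times()]).
#' @param n_snps SNPs in the GWAS panel (default 50).
#' @param ld_scale_bp Distance scale of LD decay, `exp(-d / ld_scale_bp)`
#'   (default 80 kb, giving mean off-diagonal r-squared near 0.2 across a
#'   200 kb locus).
#' @param interactions_per_gene Mean number of capture interactions per bait.
#' @param tad_size_bp Mean TAD size (default 800 kb).
#' @param compartment_bin_bp Eigen-score bin width (default 100 kb).
#' @return A `scaffold_bundle`: a list with tibbles `fragments`, `genes`,
#'   `peaks`, `interactions`, `tads_by_time`, `compartments_by_time`,
#'   `compartment_scores`, `snps`, matrix `ld`, and list `truth`.
#' @export
simulate_genome <- function(chrom_length = 1e7,
                            n_fragments = 2000,
                            n_genes = 50,
                            n_peaks = 300,
                            seed = 1,
                            times = default_times(),
                            n_snps = 50,
                            ld_scale_bp = 8e4,
                            interactions_per_gene = 3,
                            tad_size_bp = 8e5,
                            compartment_bin_bp = 1e5) {
  if (chrom_length <= 0) abort("chrom_length must be positive")
  if (n_fragments < 1) abort("n_fragments must be at least 1")
  if (n_genes < 0 || n_peaks < 0 || n_snps < 0) {
    abort("feature counts must be non-negative")
  }
  if (n_fragments > chrom_length) abort("more fragments than base pairs")
  set.seed(derive_seed(seed, "genome"))
  chrom <- "chrS"

  ## fragments: random partition, mean length = chrom_length / n_fragments
  breaks <- sort(sample.int(chrom_length - 1L, n_fragments - 1L))
  starts <- c(0L, breaks)
  ends <- c(breaks, as.integer(chrom_length))
  fragments <- tibble(
    fragment_id = seq_len(n_fragments),
    chrom = chrom, start = starts, end = ends
  )
  frag_mid <- (fragments$start + fragments$end) / 2

  locate_fragment <- function(pos) {
    findInterval(pos, c(fragments$start, chrom_length), rightmost.closed = TRUE)
  }

  ## genes: TSS uniform; bait fragment = fragment containing the TSS.
  ## A few genes share a bait so multi-gene baits occur.
  genes <- tibble()
  if (n_genes > 0) {
    tss <- sort(sample.int(chrom_length - 1L, n_genes))
    bait <- locate_fragment(tss)
    if (n_genes >= 4) {
      # force one shared bait: move the second gene's TSS into gene 1's fragment
      f1 <- bait[1]
      tss[2] <- as.integer((fragments$start[f1] + fragments$end[f1]) %/% 2)
      bait[2] <- f1
    }
    genes <- tibble(
      gene_id = sprintf("gene_%03d", seq_len(n_genes)),
      chrom = chrom, tss = tss,
      strand = sample(c("+", "-"), n_genes, replace = TRUE),
      bait_fragment_id = bait
    )
  }

  ## interactions: baits reach otherEnd fragments across the distance strata
  interactions <- tibble()
  if (n_genes > 0) {
    bait_frags <- unique(genes$bait_fragment_id)
    recs <- list()
    k <- 0L
    for (bf in bait_frags) {
      n_int <- max(1L, stats::rpois(1, interactions_per_gene))
      for (i in seq_len(n_int)) {
        d <- round(exp(runif(1, log(2e4), log(3e6))))
        target <- frag_mid[bf] + sample(c(-1, 1), 1) * d
        if (target < 0 || target >= chrom_length) target <- frag_mid[bf] + d *
            (if (frag_mid[bf] > chrom_length / 2) -1 else 1)
        of <- locate_fragment(min(max(target, 0), chrom_length - 1))
        if (of == bf) next
        k <- k + 1L
        recs[[k]] <- tibble(bait_fragment_id = bf, oe_fragment_id = of)
      }
    }
    interactions <- list_rbind(recs) |> distinct()
    # a bait-to-bait pair, if geometry allows, to exercise duplication rules
    if (length(bait_frags) >= 2) {
      interactions <- bind_rows(
        interactions,
        tibble(bait_fragment_id = bait_frags[1], oe_fragment_id = bait_frags[2])
      ) |> distinct()
    }
    n_int <- nrow(interactions)
    # CHiCAGO-like scores: most interactions clear the retention threshold at
    # their peak time, a minority never do
    max_score <- ifelse(runif(n_int) < 0.85, runif(n_int, 5.5, 15),
                        runif(n_int, 0.5, 4.5))
    peak_t <- sample(seq_along(times), n_int, replace = TRUE)
    score <- t(vapply(seq_len(n_int), function(i) {
      prof <- exp(-abs(seq_along(times) - peak_t[i]) / 2)
      max_score[i] * prof / max(prof)
    }, numeric(length(times))))
    colnames(score) <- paste0("score_t", seq_along(times) - 1)
    interactions <- interactions |>
      mutate(interaction_id = sprintf("int_%04d", seq_len(n_int)),
             .before = 1) |>
      bind_cols(as_tibble(score))
  }

  ## peaks: ~60% inside otherEnd fragments (link fodder), rest anywhere
  peaks <- tibble()
  if (n_peaks > 0) {
    oe_pool <- unique(interactions$oe_fragment_id)
    host <- integer(n_peaks)
    in_oe <- runif(n_peaks) < 0.6 & length(oe_pool) > 0
    host[in_oe] <- sample(oe_pool, sum(in_oe), replace = TRUE)
    host[!in_oe] <- sample.int(n_fragments, sum(!in_oe), replace = TRUE)
    fl <- fragments$end[host] - fragments$start[host]
    w <- pmin(pmax(round(runif(n_peaks, 200, 800)), 50), pmax(fl - 2, 1))
    off <- floor(runif(n_peaks) * pmax(fl - w, 1))
    peaks <- tibble(
      peak_id = sprintf("peak_%04d", seq_len(n_peaks)),
      chrom = chrom,
      start = as.integer(fragments$start[host] + off),
      end = as.integer(fragments$start[host] + off + w),
      fragment_id = host
    )
  }

  ## TADs: base partition jittered per time point; the 24 h track gets a
  ## boundary rearrangement so long-separation consistency drops
  n_tads <- max(2L, round(chrom_length / tad_size_bp))
  base_bounds <- sort(sample.int(chrom_length - 1L, n_tads - 1L))
  tads_by_time <- list_rbind(lapply(seq_along(times), function(ti) {
    b <- base_bounds + round(rnorm(length(base_bounds), 0, 2e3))
    if (times[ti] >= 1440) {
      drop <- sample(seq_along(b), max(1L, length(b) %/% 5))
      b <- b[-drop]
    }
    b <- sort(pmin(pmax(b, 1), chrom_length - 1))
    tibble(time = times[ti], chrom = chrom,
           start = as.integer(c(0, b)), end = as.integer(c(b, chrom_length)))
  }))

  ## compartments: smooth eigen-score per 100 kb bin, drifting over time
  n_bins <- ceiling(chrom_length / compartment_bin_bp)
  base_sc <- as.numeric(stats::filter(rnorm(n_bins + 20), rep(1 / 8, 8),
                                      sides = 1))[-seq_len(20)]
  base_sc <- base_sc / sd(base_sc)
  drift_dir <- rnorm(n_bins) / 4
  compartment_scores <- list_rbind(lapply(seq_along(times), function(ti) {
    sc <- base_sc + drift_dir * log2(1 + times[ti]) / log2(1441) +
      rnorm(n_bins, 0, 0.08)
    tibble(time = times[ti], chrom = chrom,
           start = as.integer((seq_len(n_bins) - 1) * compartment_bin_bp),
           end = as.integer(pmin(seq_len(n_bins) * compartment_bin_bp,
                                 chrom_length)),
           score = sc)
  }))
  compartments_by_time <- compartment_scores |>
    group_by(.data$time) |>
    group_modify(function(d, g) {
      lab <- ifelse(d$score >= 0, "A", "B")
      r <- rle(lab)
      idx_end <- cumsum(r$lengths)
      idx_start <- idx_end - r$lengths + 1
      tibble(chrom = d$chrom[1], start = d$start[idx_start],
             end = d$end[idx_end], label = r$values)
    }) |>
    ungroup()

  ## SNP panel: a 200 kb locus, preferentially centred on a linkable peak
  snps <- tibble()
  ld <- matrix(numeric(0), 0, 0)
  if (n_snps > 0) {
    centre <- if (n_peaks > 0) {
      as.integer((peaks$start[1] + peaks$end[1]) / 2)
    } else as.integer(chrom_length / 2)
    span <- min(2e5, chrom_length)
    lo <- max(0, min(centre - span / 2, chrom_length - span))
    pos <- sort(unique(as.integer(lo + runif(n_snps) * span)))
    while (length(pos) < n_snps) {
      pos <- sort(unique(c(pos, as.integer(lo + runif(1) * span))))
    }
    snps <- tibble(
      rsid = sprintf("rs%05d", seq_len(n_snps)),
      chrom = chrom, pos = pos,
      beta = NA_real_, se = NA_real_
    )
    r <- exp(-abs(outer(pos, pos, "-")) / ld_scale_bp)
    ld <- r * r  # Schur product of a PSD kernel with itself stays PSD
    dimnames(ld) <- list(snps$rsid, snps$rsid)
  }

  ## candidate true links: peak inside otherEnd fragment of an interaction
  ## whose bait carries a gene
  true_links <- tibble()
  if (nrow(peaks) > 0 && nrow(interactions) > 0 && nrow(genes) > 0) {
    true_links <- peaks |>
      select("peak_id", "fragment_id") |>
      inner_join(interactions |>
                   select("interaction_id", "bait_fragment_id",
                          "oe_fragment_id"),
                 by = c(fragment_id = "oe_fragment_id"),
                 relationship = "many-to-many") |>
      inner_join(genes |> select("gene_id", "bait_fragment_id"),
                 by = "bait_fragment_id",
                 relationship = "many-to-many") |>
      select("peak_id", "interaction_id", "gene_id")
  }

  structure(
    list(
      chrom = chrom, chrom_length = as.integer(chrom_length), times = times,
      fragments = fragments, genes = genes, peaks = peaks,
      interactions = interactions, tads_by_time = tads_by_time,
      compartments_by_time = compartments_by_time,
      compartment_scores = compartment_scores,
      snps = snps, ld = ld,
      truth = list(dynamic = tibble(), true_links = true_links,
                   causal_snp = NA_character_),
      seed = as.integer(seed)
    ),
    class = "scaffold_bundle"
  )
}

#' @export
print.scaffold_bundle <- function(x, ...) {
  cat("<scaffold_bundle> ", x$chrom, ": ", x$chrom_length, " bp, ",
      nrow(x$fragments), " fragments, ", nrow(x$genes), " genes, ",
      nrow(x$peaks), " peaks, ", nrow(x$interactions), " interactions, ",
      nrow(x$snps), " SNPs\n", sep = "")
  invisible(x)
}

#' Simulate time-course counts for every scaffold feature
#'
#' Each peak, interaction and gene receives a count profile over
#' `scaffold$times` x `replicates`. Dynamic features draw a latent mean
#' function from a squared-exponential Gaussian process on the
#' `log2(1 + minutes)` axis; static features have a constant latent mean.
#' Counts are negative-binomial around the exponentiated latent mean, with
#' replicates conditionally independent given the latent function.
#'
#' When `couple_links = TRUE` (default) the members of each ground-truth
#' triplet in `scaffold$truth$true_links` share a single latent function, so
#' genuinely co-regulated peak-interaction-gene triplets exist for the
#' linkage stage. Coupling is skipped when `dyn_fraction = 0`.
#'
#' @param scaffold A `scaffold_bundle`.
#' @param dyn_fraction Proportion of features that are dynamic, in \[0, 1\].
#' @param signal_var Variance of the latent GP on the natural-log scale
#'   (default 1).
#' @param lengthscale GP lengthscale on the transformed time axis
#'   (default 2).
#' @param dispersion Negative-binomial dispersion (variance =
#'   `mu + dispersion * mu^2`); 0 gives Poisson counts. Default 0.1.
#' @param replicates Replicates per time point (default 2).
#' @param base_mean Median baseline count per feature (default 200).
#' @param couple_links Share latent dynamics across ground-truth triplets.
#' @param seed Integer seed.
#' @return List with `profiles` (long tibble: `feature_id`, `kind`, `time`,
#'   `replicate`, `count`) and `truth` (tibble: `feature_id`, `kind`,
#'   `dynamic`). The truth table is also written into the returned
#'   `scaffold` copy under `truth$dynamic`.
#' @export
simulate_timecourses <- function(scaffold,
                                 dyn_fraction = 0.25,
                                 signal_var = 1,
                                 lengthscale = 2,
                                 dispersion = 0.1,
                                 replicates = 2,
                                 base_mean = 200,
                                 couple_links = TRUE,
                                 seed = 1) {
  stopifnot(inherits(scaffold, "scaffold_bundle"))
  if (replicates < 1) abort("replicates must be at least 1")
  if (dyn_fraction < 0 || dyn_fraction > 1) {
    abort("dyn_fraction must lie in [0, 1]")
  }
  set.seed(derive_seed(seed, "timecourses"))
  times <- scaffold$times
  x <- transform_times(times)
  Kse <- exp(-0.5 * outer(x, x, "-")^2 / lengthscale^2)
  Lse <- chol(Kse + diag(1e-9, length(x)))
  # `signal_var` is the realized variance of the latent over the grid, so a
  # stated signal-to-noise ratio holds for every dynamic feature (a raw GP
  # draw's sample variance is itself random and can be near zero)
  draw_latent <- function() {
    f <- drop(crossprod(Lse, rnorm(length(x))))
    s <- sd(f)
    while (s < 1e-8) {
      f <- drop(crossprod(Lse, rnorm(length(x))))
      s <- sd(f)
    }
    (f - mean(f)) / s * sqrt(signal_var)
  }

  features <- bind_rows(
    tibble(feature_id = scaffold$peaks$peak_id, kind = "peak"),
    tibble(feature_id = scaffold$interactions$interaction_id,
           kind = "interaction"),
    tibble(feature_id = scaffold$genes$gene_id, kind = "gene")
  )
  if (nrow(features) == 0) abort("scaffold has no features to simulate")

  dynamic <- runif(nrow(features)) < dyn_fraction
  names(dynamic) <- features$feature_id

  # latent function per feature; coupled triplet members share one draw
  latents <- vector("list", nrow(features))
  names(latents) <- features$feature_id
  if (couple_links && dyn_fraction > 0 &&
      nrow(scaffold$truth$true_links) > 0) {
    tl <- scaffold$truth$true_links
    for (i in seq_len(nrow(tl))) {
      ids <- c(tl$peak_id[i], tl$interaction_id[i], tl$gene_id[i])
      ids <- ids[ids %in% features$feature_id]
      if (any(!vapply(latents[ids], is.null, logical(1)))) {
        shared <- latents[ids][!vapply(latents[ids], is.null,
                                       logical(1))][[1]]
      } else {
        shared <- draw_latent()
      }
      for (id in ids) {
        if (is.null(latents[[id]])) latents[[id]] <- shared
        dynamic[id] <- TRUE
      }
    }
  }
  for (id in features$feature_id) {
    if (is.null(latents[[id]])) {
      latents[[id]] <- if (dynamic[id]) {
        draw_latent()
      } else rep(0, length(x))
    }
  }
  if (dyn_fraction == 0) {
    dynamic[] <- FALSE
    latents <- lapply(latents, function(z) rep(0, length(x)))
  }

  mu0 <- log(base_mean) + rnorm(nrow(features), 0, 0.5)
  profiles <- list_rbind(lapply(seq_len(nrow(features)), function(i) {
    mu <- exp(mu0[i] + latents[[i]])
    n <- length(times) * replicates
    mu_rep <- rep(mu, each = replicates)
    cnt <- if (dispersion > 0) {
      rnbinom(n, mu = mu_rep, size = 1 / dispersion)
    } else stats::rpois(n, mu_rep)
    tibble(feature_id = features$feature_id[i], kind = features$kind[i],
           time = rep(times, each = replicates),
           replicate = rep(seq_len(replicates), length(times)),
           count = as.numeric(cnt))
  }))

  truth <- features |> mutate(dynamic = unname(dynamic[features$feature_id]))
  scaffold$truth$dynamic <- truth
  list(profiles = profiles, truth = truth, scaffold = scaffold)
}

#' Simulate dense toy contact matrices over the time course
#'
#' One symmetric matrix per time point with the canonical distance-decay
#' profile, a shared structural component and a small time-drifting
#' component, so correlation between matrices decays with time separation
#' (the regime the stratum-adjusted correlation coefficient quantifies).
#'
#' @param n_bins Matrix dimension (default 120).
#' @param times Time grid in minutes.
#' @param drift Standard deviation of the per-time structural drift
#'   relative to the shared component (default 0.3).
#' @param seed Integer seed.
#' @return Named list of `n_bins x n_bins` symmetric matrices, one per
#'   time point.
#' @export
simulate_contact_matrices <- function(n_bins = 120, times = default_times(),
                                      drift = 0.3, seed = 1) {
  if (n_bins < 2) abort("n_bins must be at least 2")
  set.seed(derive_seed(seed, "contacts"))
  D <- abs(outer(seq_len(n_bins), seq_len(n_bins), "-"))
  decay <- 1 / (1 + D)^0.8
  sym_noise <- function() {
    z <- matrix(rnorm(n_bins^2), n_bins)
    (z + t(z)) / sqrt(2)
  }
  # structural field evolves as an AR(1) process on the transformed time
  # axis, so matrix correlation decays with time separation
  x <- transform_times(times)
  S <- sym_noise()
  mats <- vector("list", length(times))
  for (ti in seq_along(times)) {
    if (ti > 1) {
      rho <- exp(-drift * (x[ti] - x[ti - 1]))
      S <- rho * S + sqrt(1 - rho^2) * sym_noise()
    }
    m <- decay * exp(0.5 * S)
    mats[[ti]] <- (m + t(m)) / 2
  }
  names(mats) <- paste0("t", times)
  mats
}

#' Simulate GWAS summary statistics for one locus
#'
#' Generates (or reuses the scaffold's) SNP panel and fills in effect
#' estimates under a single-causal-variant model: the causal SNP has true
#' log odds ratio `beta`, and every other SNP's expected estimate is
#' attenuated by its LD with the causal variant,
#' `E[beta_j] = r2_j * beta`, with sampling noise of standard deviation
#' `se` added to every estimate.
#'
#' @param scaffold Optional `scaffold_bundle` providing the SNP panel and LD
#'   matrix; if `NULL` a free-standing panel is generated.
#' @param causal_snp rsid of the causal SNP; default the panel's central SNP.
#' @param beta True causal log odds ratio (default 0.25).
#' @param se Standard error of every estimate (default 0.05).
#' @param n_snps Panel size when no scaffold is given (default 50).
#' @param ld_scale_bp LD decay scale when no scaffold is given.
#' @param seed Integer seed.
#' @param locus_id Label written into the returned summary statistics.
#' @return List with `stats` (tibble: `rsid`, `chrom`, `pos`, `beta`, `se`,
#'   `locus_id`), `ld` (r-squared matrix) and `causal_snp`.
#' @export
simulate_gwas_locus <- function(scaffold = NULL,
                                causal_snp = NULL,
                                beta = 0.25,
                                se = 0.05,
                                n_snps = 50,
                                ld_scale_bp = 8e4,
                                seed = 1,
                                locus_id = "locus_1") {
  if (se <= 0) abort("se must be positive")
  if (is.null(scaffold)) {
    if (n_snps < 1) abort("n_snps must be at least 1")
    scaffold <- simulate_genome(chrom_length = max(2e5, n_snps * 10),
                                n_fragments = 10, n_genes = 0, n_peaks = 0,
                                n_snps = n_snps, ld_scale_bp = ld_scale_bp,
                                seed = derive_seed(seed, "panel"))
  }
  snps <- scaffold$snps
  ld <- scaffold$ld
  if (nrow(snps) < 1) abort("scaffold has no SNP panel")
  if (is.null(causal_snp)) {
    causal_snp <- snps$rsid[ceiling(nrow(snps) / 2)]
  }
  if (!causal_snp %in% snps$rsid) abort("causal_snp not in the SNP panel")
  set.seed(derive_seed(seed, "gwas"))
  r2 <- setNames(ld[, causal_snp], rownames(ld))
  # sampling errors of marginal effect estimates are correlated through LD
  # (cov[beta_hat_i, beta_hat_j] ~ r_ij * se^2), so noise is drawn from a
  # multivariate normal with correlation r = sqrt(r^2)
  R <- sqrt(ld)
  Lr <- chol(R + diag(1e-8, nrow(R)))
  noise <- se * drop(crossprod(Lr, rnorm(nrow(snps))))
  stats_tbl <- snps |>
    mutate(beta = unname(r2[.data$rsid]) * !!beta +
             unname(noise[match(.data$rsid, rownames(ld))]),
           se = !!se, locus_id = locus_id)
  list(stats = stats_tbl, ld = ld, causal_snp = causal_snp)
}
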