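# Readers and writers for the plain-text exchange formats (BED, TSV, JSON),
# plus the end-to-end pipeline driver.
#
# Conventions: all genomic coordinates are 0-based half-open internally;
# TSV files are tab-separated with a required header, '#' comments and no
# quoting; GWAS positions arriving 1-based are converted at ingest.

#' Read a BED file of intervals
#'
#' @param path File path; 3+ tab-separated columns, 0-based half-open.
#' @return Tibble with `chrom`, `start`, `end`, optional `name`, and the
#'   source `line` number for diagnostics.
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  keep <- !grepl("^#", lines) & nzchar(lines)
  idx <- which(keep)
  if (length(idx) == 0) {
    return(tibble(chrom = character(), start = integer(), end = integer(),
                  line = integer()))
  }
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  out <- list_rbind(lapply(seq_along(parts), function(i) {
    p <- parts[[i]]
    ln <- idx[i]
    if (length(p) < 3) {
      abort(sprintf("%s line %d: expected at least 3 columns", path, ln))
    }
    s <- suppressWarnings(as.numeric(p[2])); e <- suppressWarnings(as.numeric(p[3]))
    if (is.na(s) || is.na(e) || s != floor(s) || e != floor(e)) {
      abort(sprintf("%s line %d: non-integer coordinates", path, ln))
    }
    if (s >= e) {
      abort(sprintf("%s line %d: start >= end (empty interval)", path, ln))
    }
    tibble(chrom = p[1], start = as.integer(s), end = as.integer(e),
           name = if (length(p) >= 4) p[4] else NA_character_, line = ln)
  }))
  if (all(is.na(out$name))) out$name <- NULL
  out
}

#' Write intervals as BED
#'
#' @param intervals Tibble with `chrom`, `start`, `end`, optional `name`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  cols <- intersect(c("chrom", "start", "end", "name"), names(intervals))
  readr::write_tsv(intervals[cols], path, col_names = FALSE)
  invisible(path)
}

#' Write a long profile table as a wide counts TSV
#'
#' One row per feature; count columns named `t<minutes>_r<replicate>`.
#'
#' @param profiles Long tibble (`feature_id`, `kind`, `time`, `replicate`,
#'   `count`).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_counts <- function(profiles, path) {
  wide <- profiles |>
    mutate(col = sprintf("t%g_r%d", .data$time, .data$replicate)) |>
    select("feature_id", "kind", "col", "count") |>
    pivot_wider(names_from = "col", values_from = "count") |>
    arrange(.data$feature_id)
  readr::write_tsv(wide, path)
  invisible(path)
}

#' Read a wide counts TSV back into long form
#'
#' @param path File written by [write_counts()].
#' @return Long tibble (`feature_id`, `kind`, `time`, `replicate`, `count`).
#' @export
read_counts <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  wide <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  cc <- grep("^t[0-9.]+_r[0-9]+$", names(wide), value = TRUE)
  if (length(cc) == 0) abort(sprintf("%s: no t<min>_r<rep> count columns", path))
  wide |>
    pivot_longer(all_of(cc), names_to = "col", values_to = "count") |>
    mutate(time = as.numeric(sub("^t([0-9.]+)_r[0-9]+$", "\\1", .data$col)),
           replicate = as.integer(sub("^t[0-9.]+_r([0-9]+)$", "\\1",
                                      .data$col))) |>
    select("feature_id", "kind", "time", "replicate", "count") |>
    arrange(.data$feature_id, .data$time, .data$replicate)
}

#' Write interaction records with per-time scores
#'
#' Emits bait and otherEnd fragment coordinates, the bait's gene ids
#' (comma-separated) and one `score_t<i>` column per time point.
#'
#' @param interactions Interaction tibble (fragment ids + `score_t*`).
#' @param fragments,genes Scaffold tables supplying coordinates and the
#'   bait-to-gene mapping.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_interactions <- function(interactions, fragments, genes, path) {
  frag <- fragments |> select("fragment_id", "chrom", "start", "end")
  gmap <- genes |>
    group_by(.data$bait_fragment_id) |>
    summarise(bait_gene_ids = paste(.data$gene_id, collapse = ","),
              .groups = "drop")
  out <- interactions |>
    left_join(frag |> rename(chrom_bait = "chrom", start_bait = "start",
                             end_bait = "end"),
              by = c(bait_fragment_id = "fragment_id")) |>
    left_join(frag |> rename(chrom_oe = "chrom", start_oe = "start",
                             end_oe = "end"),
              by = c(oe_fragment_id = "fragment_id")) |>
    left_join(gmap, by = "bait_fragment_id")
  readr::write_tsv(out, path)
  invisible(path)
}

#' Read interaction records
#'
#' @param path File path.
#' @param times Optional time grid; when given, the number of `score_t*`
#'   columns must match its length.
#' @return Interaction tibble.
#' @export
read_interactions <- function(path, times = NULL) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  sc <- grep("^score_t", names(out), value = TRUE)
  if (length(sc) == 0) abort(sprintf("%s: missing score_t* columns", path))
  if (!is.null(times) && length(sc) != length(times)) {
    abort(sprintf("%s: %d score columns but %d time points configured",
                  path, length(sc), length(times)))
  }
  out
}

#' Read GWAS summary statistics
#'
#' Expects columns `rsid`, `chrom`, `pos`, `beta`, `se` (and optional
#' `locus_id`). Positions are treated as 1-based and converted to the
#' package's 0-based convention.
#'
#' @param path File path.
#' @return Tibble with 0-based `pos` and `V = se^2` appended.
#' @export
read_gwas <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  out <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  need <- c("rsid", "chrom", "pos", "beta", "se")
  miss <- setdiff(need, names(out))
  if (length(miss)) {
    abort(sprintf("%s: missing column(s) %s", path,
                  paste(miss, collapse = ", ")))
  }
  out |> mutate(pos = as.integer(.data$pos) - 1L, V = .data$se^2)
}

#' Write / read a square LD (r-squared) matrix as TSV
#'
#' @param ld Symmetric matrix with rsid dimnames.
#' @param path File path.
#' @return `path` (writer) or the matrix (reader).
#' @export
write_ld <- function(ld, path) {
  df <- as_tibble(ld, rownames = "rsid")
  readr::write_tsv(df, path)
  invisible(path)
}

#' @rdname write_ld
#' @export
read_ld <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  df <- readr::read_tsv(path, comment = "#", show_col_types = FALSE)
  m <- as.matrix(df[, -1])
  rownames(m) <- df$rsid
  m
}

#' Serialise a scaffold bundle to a directory of plain-text files
#'
#' Writes peaks BED, fragment BED, genes TSV, interactions TSV, GWAS TSV,
#' LD TSV, per-time TAD/compartment tracks and a truth JSON; the reverse
#' reader reassembles an identical bundle.
#'
#' @param scaffold A `scaffold_bundle`.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_scaffold <- function(scaffold, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  p <- function(f) file.path(dir, f)
  write_bed(scaffold$peaks |> rename(name = "peak_id"), p("peaks.bed"))
  readr::write_tsv(scaffold$peaks, p("peaks.tsv"))
  readr::write_tsv(scaffold$fragments, p("fragments.tsv"))
  readr::write_tsv(scaffold$genes, p("genes.tsv"))
  if (nrow(scaffold$interactions) > 0) {
    write_interactions(scaffold$interactions, scaffold$fragments,
                       scaffold$genes, p("interactions.tsv"))
  }
  readr::write_tsv(scaffold$tads_by_time, p("tads.tsv"))
  readr::write_tsv(scaffold$compartments_by_time, p("compartments.tsv"))
  readr::write_tsv(scaffold$compartment_scores, p("compartment_scores.tsv"))
  if (nrow(scaffold$snps) > 0) {
    readr::write_tsv(scaffold$snps, p("gwas.tsv"))
    write_ld(scaffold$ld, p("ld.tsv"))
  }
  meta <- list(chrom = scaffold$chrom, chrom_length = scaffold$chrom_length,
               times = scaffold$times, seed = scaffold$seed,
               truth = list(
                 dynamic = scaffold$truth$dynamic,
                 true_links = scaffold$truth$true_links,
                 causal_snp = scaffold$truth$causal_snp))
  jsonlite::write_json(meta, p("scaffold.json"), auto_unbox = TRUE,
                       digits = NA, null = "null", na = "null")
  invisible(dir)
}

#' @rdname write_scaffold
#' @export
read_scaffold <- function(dir) {
  p <- function(f) file.path(dir, f)
  meta <- jsonlite::read_json(p("scaffold.json"), simplifyVector = TRUE)
  rd <- function(f) if (file.exists(p(f))) {
    readr::read_tsv(p(f), show_col_types = FALSE)
  } else tibble()
  interactions <- if (file.exists(p("interactions.tsv"))) {
    read_interactions(p("interactions.tsv")) |>
      select("interaction_id", "bait_fragment_id", "oe_fragment_id",
             starts_with("score_t"))
  } else tibble()
  snps <- rd("gwas.tsv")
  ld <- if (file.exists(p("ld.tsv"))) read_ld(p("ld.tsv")) else {
    matrix(numeric(0), 0, 0)
  }
  truth <- list(
    dynamic = as_tibble(meta$truth$dynamic),
    true_links = as_tibble(meta$truth$true_links),
    causal_snp = meta$truth$causal_snp %||% NA_character_
  )
  structure(list(
    chrom = meta$chrom, chrom_length = as.integer(meta$chrom_length),
    times = as.numeric(meta$times),
    fragments = rd("fragments.tsv"), genes = rd("genes.tsv"),
    peaks = rd("peaks.tsv"), interactions = interactions,
    tads_by_time = rd("tads.tsv"),
    compartments_by_time = rd("compartments.tsv"),
    compartment_scores = rd("compartment_scores.tsv"),
    snps = snps, ld = ld, truth = truth, seed = as.integer(meta$seed)
  ), class = "scaffold_bundle")
}

#' Pipeline configuration
#'
#' Collects every tunable threshold with the defaults used throughout:
#' interaction score cut 5, per-replicate gene total 10, LR-test alpha
#' 0.05, inclusive clustering LR 1, link correlation 0.5, LD expansion
#' r-squared 0.8, prior effect variance 0.04, credible level 0.99,
#' reciprocal overlap 0.9.
#'
#' @param outdir Output directory.
#' @param seed Integer seed driving every stochastic stage.
#' @param times Time grid in minutes.
#' @param n_fragments,n_genes,n_peaks,chrom_length Scaffold size.
#' @param dyn_fraction,replicates Generator settings.
#' @param k Cluster count.
#' @param score_threshold,min_gene_total,alpha,lr_inclusive,r_link,r2_ld,omega,level,min_frac
#'   Stage thresholds (see description).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(outdir = tempfile("chromdyn_run_"),
                            seed = 1,
                            times = default_times(),
                            chrom_length = 1e7,
                            n_fragments = 400, n_genes = 25, n_peaks = 100,
                            dyn_fraction = 0.3, replicates = 2, k = 4,
                            score_threshold = 5, min_gene_total = 10,
                            alpha = 0.05, lr_inclusive = 1, r_link = 0.5,
                            r2_ld = 0.8, omega = 0.04, level = 0.99,
                            min_frac = 0.9) {
  cfg <- as.list(environment())
  stopifnot(alpha > 0, alpha < 1, level > 0, level < 1, omega >= 0,
            r2_ld >= 0, r2_ld <= 1, min_frac > 0, min_frac <= 1)
  structure(cfg, class = "pipeline_config")
}

#' Run the full synthetic pipeline
#'
#' Simulates a scaffold and time courses, classifies dynamics for every
#' feature kind, clusters dynamic non-promoter peaks, builds and correlates
#' links with background enrichment, constructs the credible SNP set,
#' prioritises SNP-bearing peaks, computes TAD/compartment consistency and
#' the compartment trend, and writes every artefact plus a manifest to
#' `config$outdir`.
#'
#' @param config A [pipeline_config()].
#' @return Invisibly, a list of all in-memory results (`scaffold`, `calls`,
#'   `clusters`, `links`, `enrichment`, `credible`, `hits`, `report`,
#'   `structure`).
#' @export
run_pipeline <- function(config = pipeline_config()) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outdir, f)

  ## stage: simulate
  scaffold <- simulate_genome(
    chrom_length = config$chrom_length, n_fragments = config$n_fragments,
    n_genes = config$n_genes, n_peaks = config$n_peaks,
    times = config$times, seed = config$seed)
  sim <- simulate_timecourses(scaffold, dyn_fraction = config$dyn_fraction,
                              replicates = config$replicates,
                              seed = config$seed)
  scaffold <- sim$scaffold
  gwas <- simulate_gwas_locus(scaffold, seed = config$seed)
  scaffold$snps <- gwas$stats |> select(-"locus_id")
  scaffold$truth$causal_snp <- gwas$causal_snp
  write_scaffold(scaffold, out("scaffold"))
  write_counts(sim$profiles, out("counts.tsv"))

  ## stage: dynamics
  calls <- call_dynamics(sim$profiles, alpha = config$alpha,
                         seed = config$seed)
  readr::write_tsv(tidy(calls), out("calls.tsv"))

  ## stage: cluster
  retained <- prefilter_for_clustering(
    calls, scaffold$peaks, scaffold$genes,
    lr_threshold = config$lr_inclusive)
  clusters <- NULL
  if (length(retained) >= config$k) {
    clusters <- cluster_profiles(
      sim$profiles |> filter(.data$feature_id %in% retained),
      k = config$k, seed = config$seed)
    readr::write_tsv(tidy(clusters), out("clusters.tsv"))
  }

  ## stage: linkage
  filt <- filter_features(
    scaffold$interactions,
    sim$profiles |> filter(.data$kind == "gene"),
    bait_fragments = unique(scaffold$genes$bait_fragment_id),
    score_threshold = config$score_threshold,
    min_gene_total = config$min_gene_total)
  links <- build_links(scaffold$peaks, filt$interactions, scaffold$genes,
                       scaffold$fragments, gene_ids = filt$gene_ids) |>
    correlate_links(sim$profiles)
  enrichment <- background_enrichment(links, sim$profiles,
                                      n_draws = max(2000, nrow(links)),
                                      seed = config$seed)
  readr::write_tsv(links, out("links.tsv"))
  jsonlite::write_json(enrichment$strata, out("enrichment.json"),
                       auto_unbox = TRUE, digits = 10, na = "null")

  ## stage: finemap
  credible <- credible_set(gwas$stats, level = config$level,
                           omega = config$omega)
  readr::write_tsv(tidy(credible), out("credible_sets.tsv"))

  ## stage: prioritise
  cred_snps <- tidy(credible) |>
    filter(.data$in_set) |>
    select("rsid", "chrom", "pos")
  pairs <- overlap_snps_peaks(cred_snps, scaffold$peaks)
  hits <- assign_genes(pairs, links, r_threshold = config$r_link)
  comp <- compartment_membership(cred_snps, scaffold$compartments_by_time)
  readr::write_tsv(hits, out("hits.tsv"))
  report <- summary_report(
    ratios = tibble(
      name = c("dynamic_peaks_bic", "dynamic_peaks_lr"),
      numerator = c(
        sum(calls$dynamic_by_bic[calls$kind == "peak"]),
        sum(calls$dynamic_by_lr[calls$kind == "peak"])),
      denominator = sum(calls$kind == "peak")),
    hits = if (nrow(hits) > 0) hits else NULL,
    compartment_classes = comp$classes)
  jsonlite::write_json(report, out("report.json"), auto_unbox = TRUE,
                       digits = 10, na = "null")

  ## stage: structure
  tad_consistency <- consistency_by_time(scaffold$tads_by_time,
                                         min_frac = config$min_frac)
  trend <- compartment_corr_trend(scaffold$compartment_scores)
  mats <- simulate_contact_matrices(times = config$times,
                                    seed = config$seed)
  scc_adjacent <- scc(mats[[1]], mats[[2]])
  readr::write_tsv(tad_consistency, out("tad_consistency.tsv"))
  jsonlite::write_json(
    list(slope = trend$slope, intercept = trend$intercept,
         scc_adjacent = scc_adjacent),
    out("structure.json"), auto_unbox = TRUE, digits = 10)

  ## manifest
  arte <- list.files(config$outdir, recursive = TRUE, full.names = TRUE)
  arte <- arte[basename(arte) != "manifest.json"]
  manifest <- list(
    package_version = as.character(utils::packageVersion("chromdyn")),
    config = unclass(config)[setdiff(names(config), "outdir")],
    coordinate_convention = "0-based half-open",
    artefacts = tibble(file = sub(paste0("^", config$outdir, "/?"), "", arte),
                       md5 = unname(tools::md5sum(arte))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = 10)

  invisible(list(scaffold = scaffold, profiles = sim$profiles,
                 truth = sim$truth, calls = calls, clusters = clusters,
                 links = links, enrichment = enrichment, credible = credible,
                 hits = hits, report = report,
                 structure = list(tad_consistency = tad_consistency,
                                  trend = trend,
                                  scc_adjacent = scc_adjacent)))
}
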