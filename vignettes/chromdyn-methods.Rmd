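---
title: "Models and methods behind chromdyn"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind chromdyn}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(chromdyn)
library(dplyr)
```

`chromdyn` implements the downstream statistical layer for a stimulated
CD4+ T-cell multi-omic time course: chromatin accessibility (ATAC-seq),
promoter-capture chromatin interactions (CHi-C), nascent expression
(nuclear RNA-seq) and Hi-C-derived higher-order structure, all sampled at
0, 20, 60, 120, 240 and 1440 minutes after CD3/CD28 stimulation, plus a
GWAS fine-mapping and variant-prioritisation layer. This vignette explains
each model, the tunable parameters and their defaults, the numerical
choices, and what the synthetic-data generator does and does not emulate.

## Dynamic versus static profiles: GP model selection

Each feature's time course (a peak, an interaction, or a gene) is reduced
to a normalised series: counts are scaled to counts-per-million within
each library (one `kind` x replicate x time combination), transformed by
`log2(x + 1)` and mean-centred per feature. Centring lets both models be
zero-mean; the CPM step makes calls invariant to global rescaling of
counts, which is asserted by a test.

Two Gaussian-process regression models are fitted to every centred series,
using all replicate observations jointly (n = replicates x time points):

* **dynamic** — squared-exponential (RBF) kernel plus white noise; three
  hyperparameters (signal variance, lengthscale, noise variance), k = 3;
* **static** — pure white noise; one hyperparameter, k = 1, whose maximum
  likelihood estimate is the closed form `mean(y^2)`.

The time axis is `log2(1 + minutes)` by default: the raw grid compresses
five of six observations into the first four hours, and the log transform
roughly equalises the spacing. Raw hours are available via
`time_transform = "hours"`.

Model choice uses `BIC = k ln(n) - 2 ln(L)` (smaller favoured), and a
stricter likelihood-ratio statistic `LR = 2 (ln L_RBF - ln L_static)`,
clipped at zero and referred to the upper tail of chi-squared with one
degree of freedom at alpha = 0.05. The LR is non-negative by construction
because the optimiser always evaluates one start pinned at the static
optimum (signal variance at its lower bound), making the static model an
exactly nested boundary case.

**Optimisation.** Bounded L-BFGS-B on log-hyperparameters with analytic
gradients, five starts (the data-driven start, the static boundary start,
and three seeded log-uniform draws). Variances are bounded to
[1e-4, 1e4] and the lengthscale to [0.1, 10] times the transformed-axis
span; the lower lengthscale bound keeps the kernel from chasing
replicate-level noise. A test suite compares the optimised likelihood of
tens of profiles against a 20^3 log-spaced grid search and requires the
optimiser never to fall more than 1e-3 nats below the grid.

**Calibration at this design.** With six time points and two replicates
the LR null distribution is more conservative than the asymptotic
half-and-half mixture of a point mass and chi-squared(1): in simulation
roughly 70% of null LR values are exactly zero and the empirical type-I
error at alpha = 0.05 is about 0.015 (the asymptotic mixture would give
0.025). This is a property of the test at small n, not of the optimiser
(verified against the grid oracle) and not of the count noise (an ideal
Gaussian null reproduces it). Power is high regardless: at a
signal-to-noise variance ratio of ten the LR rule recovers about 98-99% of
dynamic features.

## Clustering accessibility archetypes

Dynamic, non-promoter peaks are clustered with a Gaussian-process mixture
model. The pre-filter keeps peaks whose dynamic-over-static improvement
exceeds an inclusive threshold of 1 nat on the LR scale (deliberately
looser than the chi-squared cut) and whose interval avoids every gene's
promoter window. The promoter window is strand-aware: `[TSS - 1000 bp,
TSS + 500 bp)` on the plus strand, mirrored on the minus strand. The
bracket convention for the window is ambiguous in common usage (upstream
versus downstream of the TSS versus the gene body); the strand-aware TSS
window is this package's documented choice, and both arms are
configurable.

The mixture model treats each replicate-averaged, normalised profile as a
noisy observation of one of K latent mean curves. Each curve carries a
squared-exponential GP prior on the transformed time grid (lengthscale
one third of the axis span by default) and the noise is shared and
isotropic. Fitting is EM with maximum-a-posteriori updates of the curves;
the penalised log-likelihood objective is recorded per iteration and is
non-decreasing (asserted by a test). Initialisation is k-means on the
profile vectors under the caller's seed; EM stops at a relative objective
change below 1e-6 or 500 iterations. K defaults to 6 — stimulated T-cell
accessibility data show about six broad temporal patterns (up, down,
transient up, transient down, late up, late down) — but K is a free
parameter and no automatic selection is attempted.

## Peak-interaction-gene links

Links connect the three assays through restriction-fragment geometry:
an ATAC peak lying wholly inside an otherEnd fragment is joined to every
retained interaction originating at that fragment and to every gene on the
interaction's bait (baits carrying several genes expand to one link per
gene, since downstream prioritisation is per-gene). Retention filters
follow the printed inequalities of the upstream processing conventions:
interactions need a confidence score strictly above 5 at one or more time
points; genes need a total count of at least 10 in *every* replicate;
bait-to-bait interactions are registered twice with the roles swapped.

Per link, Pearson correlations are computed between the replicate-averaged
normalised series of peak and interaction, peak and gene, and gene and
interaction. Links are stratified by the separation of the bait and
otherEnd fragment midpoints with half-open boundaries [0, 200 kb),
[200, 500 kb), [500 kb, 1 Mb), [1, 5 Mb); links at 5 Mb or beyond are
dropped. Midpoint-to-midpoint distance is the default anchor because the
fragment, not the TSS, is the unit of the capture design.

The enrichment null draws `n_draws` random feature pairs of the relevant
kinds uniformly, with no genomic restriction, and compares each stratum's
observed correlations with the null by a two-sided Wilcoxon rank-sum test.
`n_draws` defaults to `max(10 000, number of links)`. Fold changes over
time are summarised as `log2((max + 1) / (min + 1))` on the count scale;
max-over-min is the default (last-versus-first is a caller option, since
either reading of a "fold change across the time course" is defensible).

## Fine-mapping and prioritisation

For a SNP with estimated log odds ratio beta and variance V = se^2, the
approximate Bayes factor in favour of association is

  sqrt(V / (V + omega)) * exp(omega * beta^2 / (2 V (V + omega)))

with prior effect variance omega = 0.04 by default. The exponent is
evaluated in log space because GWAS-scale Z values overflow the double
range. Posteriors are Bayes factors normalised within the locus; the
credible set is the minimal Bayes-factor-ranked prefix whose cumulative
posterior reaches the level (0.99 by default; the level is a parameter
because array-era credible sets were also published at 95%). Ties are
broken by position then rsid so output is deterministic.

Prioritisation intersects credible (or LD-expanded, r^2 >= 0.8) SNPs with
peak intervals under the half-open convention, assigns genes through links
whose three correlations all reach 0.5 (signed by default; an
absolute-value mode exists), and classifies each SNP's A/B compartment
trajectory as consistent A, consistent B, or switching. Reported
percentages round half away from zero, matching how such ratios are
conventionally printed (10.53% prints as 11%).

## Higher-order structure

TAD and compartment stability between time points is the fraction of one
track's intervals that have a 90% reciprocal-overlap partner in the other
track — asymmetric by design, since the denominator is the first track's
interval count. Compartment dynamics are summarised by Pearson
correlations of binned eigen-scores between all sample pairs (each
sample's sign is oriented against the first sample, PCA signs being
arbitrary) with an OLS line of correlation against absolute time
separation. Contact-map reproducibility uses a stratum-adjusted
correlation coefficient: per off-diagonal distance d, the Pearson
correlation r_d of paired entries, combined with weights
N_d * sd_a,d * sd_b,d and zero-variance strata skipped. This is a
simplified SCC — it omits the 2D mean-filter smoothing of the full
HiCRep procedure — and is labelled as such.

## The synthetic generator

`simulate_genome()` builds one toy chromosome (10 Mb by default): a random
fragment tiling with mean length `chrom_length / n_fragments`
(restriction-site geometry is not modelled), genes whose TSS fragment is
their bait, peaks placed wholly inside fragments (60% of them inside
otherEnd fragments so that links exist), interactions spanning 20 kb-3 Mb
with confidence scores that clear the retention threshold for ~85% of
records, per-time TAD tracks (jittered boundaries, with a deliberate
boundary rearrangement at 24 h), drifting compartment eigen-scores on a
100 kb grid, and a 200 kb SNP panel with LD `r = exp(-distance / 80 kb)`
(mean off-diagonal r^2 ~ 0.2).

`simulate_timecourses()` gives every feature a latent mean on the
`log2(1 + minutes)` axis: dynamic features draw from a squared-exponential
GP (lengthscale 2 by default) and the draw is rescaled to an exact sample
variance of `signal_var` over the grid, so a stated signal-to-noise ratio
holds for every dynamic feature rather than on average (a raw GP draw's
realized variance is itself random and can be near zero, which would make
"dynamic" labels vacuous for a tail of features). Counts are
negative-binomial around the exponentiated latent mean (dispersion 0.1 by
default, i.e. log-scale noise variance ~0.1 against the default signal
variance 1 — a signal-to-noise ratio of ten); replicates are conditionally
independent given the latent curve, since the replicate correlation
structure of the real libraries is not known. Members of ground-truth
peak-interaction-gene triplets share one latent curve so genuinely
co-regulated links exist for the linkage stage.

`simulate_gwas_locus()` fills the panel with summary statistics under a
single-causal-variant model: the expected estimate at SNP j is
`r2_j * beta` (attenuation by LD with the causal variant), and sampling
noise is drawn from a multivariate normal with correlation r — the
sampling covariance of marginal effect estimates is proportional to LD,
and drawing independent noise instead would misrank the causal variant
far more often than real summary statistics do.

**What the generator does not emulate:** read-level noise, mappability
and GC artefacts, replicate batch effects, trans-chromosomal contacts,
multi-causal loci, and realistic gene/peak density. Passing tests
therefore demonstrate the correctness and calibration of the statistical
machinery under its stated assumptions, not performance on real
sequencing data.

## Problem sizes used in the test and acceptance runs

The shipped test suite and `scripts/acceptance.R` run everything at desk
scale, chosen so each property is measured with useful precision while the
whole suite stays fast: 1000 static profiles for the type-I measurement,
500 dynamic profiles for power, 200 simulated loci for credible-set
coverage, 600 profiles across six archetypes for clustering recovery, and
a 30 Mb scaffold (~350 genes, 1200 peaks) yielding several hundred links
for the enrichment comparison.

## Worked example

```{r example, eval = FALSE}
sc <- simulate_genome(n_fragments = 400, n_genes = 25, n_peaks = 100,
                      seed = 1)
sim <- simulate_timecourses(sc, dyn_fraction = 0.3, seed = 1)
calls <- call_dynamics(sim$profiles)
glance(calls)

retained <- prefilter_for_clustering(calls, sc$peaks, sc$genes)
clusters <- cluster_profiles(
  dplyr::filter(sim$profiles, feature_id %in% retained), k = 4, seed = 1)
autoplot(clusters)

res <- run_pipeline(pipeline_config(seed = 1))
res$report
```
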