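---
title: "Gene-family abundance fluctuations and horizontal transfer dynamics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Gene-family abundance fluctuations and horizontal transfer dynamics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(famfluct)
```

## The question

Prokaryotic genomes gain and lose gene-family members mainly through
horizontal gene transfer (HGT), gene duplication and gene loss. Looked at
across many sequenced species, each family $f$ therefore has not just an
average abundance but a *fluctuation pattern*: the histogram of its copy
number $V_{f,g}$ over genomes $g$. `famfluct` implements a minimal
stochastic model that links the shape of this histogram to the underlying
transfer/duplication/loss rates, plus the statistics needed to classify real
or simulated family-by-genome count matrices by that shape.

## The collisional model

A fixed ensemble of $N$ species genomes evolves one family's copy numbers
$V_1, \dots, V_N$ through pairwise "collisions". When species $i$ and $j$
collide:

* each of $j$'s copies is transferred into $i$ with probability $p_h$
  (and vice versa) — the donor keeps its copy;
* each of $i$'s own copies is, exclusively, lost with probability $p_l$ or
  duplicated with probability $p_d$ (so $p_d + p_l \le 1$);
* all draws use the pre-collision copy numbers and both partners update
  simultaneously.

Time is measured in *sweeps* of $N$ collisions. Stationarity of the total
abundance requires the balance $p_h + p_d = p_l$, enforced by
`collision_params()`; under it the expected change of $\sum_i V_i$ per
collision is exactly zero, so the mean abundance $\lambda$ is set by the
initial condition. Each event should be read as an already-fixed change on a
species' representative genome; there is no within-population dynamics, and
families evolve independently (one simulation per family).

Mean-field predictions, all exposed as closed forms:

* $p_d = 0$: the stationary profile is Poisson($\lambda$)
  (`poisson_profile()`), a parameter-free prediction once the mean is known;
* $p_d > 0$: $\mathrm{Var}(V) = \lambda\,(1 + p_d/(p_h(1-p_h)))$
  (`stationary_variance()`) — duplication overdisperses the profile;
* in the grazing-collision limit ($p_d, p_h \to 0$ at fixed ratio) the full
  profile is a negative binomial with mean $\lambda$ and variance
  $\lambda\,(p_d + p_h)/p_h$ (`grazing_limit_profile()`, parameterized by
  moment matching: size $r = \lambda p_h / p_d$, success probability
  $q = p_h/(p_d + p_h)$).

```{r model, eval = FALSE}
p <- collision_params(p_h = 0.01, p_d = 0, N = 1000)
se <- stationary_ensemble(p, init = 30, n_sweeps = 1500, burn_in = 150,
                          snapshot_every = 25, n_reps = 8, seed = 1)
l1_to_profile(se$values, poisson_profile(30))  # ~0.02
```

### A note on time scales

The mean-field trajectory helpers (`relaxation_time_sweeps()`,
`expected_variance_trajectory()`) report the analytic relaxation time
$1/(p_h(1-p_h))$ sweeps. The microscopic simulation relaxes faster than this
expression: per species-update the centered second moment contracts by
$(1-p_h)^2 + p_h^2 = 1 - 2p_h(1-p_h)$, and with $N$ collisions per sweep each
species updates twice per sweep on average, so the fitted time constant of
the ensemble variance is $1/(4\,p_h(1-p_h))$ sweeps. The factor is forced by
consistency: the stationary variance formula above equals (inhomogeneity ÷
relaxation rate), so any implementation reproducing the stationary variance
with this collision rule must relax at the microscopic rate. The analytic
expression should therefore be read in the kinetic-equation time
normalization; the unit tests verify exponential relaxation at the
microscopic rate, and burn-in recommendations below use the measured
constant.

### Estimating stationary quantities

$\sum_i V_i$ is a martingale: it is conserved *in expectation* but performs
an unbiased random walk (variance growing linearly in collisions), so at
$N = 1000$ the ensemble mean drifts by $\pm 1$–3 copies over $10^3$–$10^4$
sweeps. `stationary_ensemble()` therefore pools abundance snapshots taken
about one relaxation time apart over the post-burn-in window and across
replicate runs; the pooled mean is an unbiased, minimum-fuss ergodic
estimator whose Monte-Carlo error shrinks with the number of replicates.
Default burn-ins in the tests and the acceptance script are six *measured*
relaxation times ($6/(4p_h(1-p_h))$ sweeps).

### Phylogeny-biased collisions

Real transfer rates decay with phylogenetic distance. `distance_kernel()`
builds pair weights $W_{ij} = e^{-d_{ij}/d_0}$ from a distance matrix (the
functional form is this package's choice; any symmetric non-negative weight
matrix is accepted), and `simulate_family(kernel = W)` picks colliding pairs
with probability proportional to $W_{ij}$. With $p_d = 0$ the stationary
profile remains Poisson under such biases, which the test suite checks.

## Abundance-fluctuation statistics

Family abundance scales with genome size, so all statistics are computed
inside sliding bins of genomes with similar size (total assigned domains).
Defaults: bin width 390 domains, step 100 domains (overlapping bins; the
step is this package's choice), minimum occupancy 10 genomes per retained
bin. For bin $b$ with $n_b$ genomes, of which $n_b^+$ carry the family:

* sampling weight $w_{f,b} = n_b n_b^+ / \sum_b n_b^2$,
  $w_f = \sum_b w_{f,b} \in [0,1]$ — how well the family's histogram is
  sampled;
* $L_{f,b} = \tfrac12 \sum_{v=0}^{450} |p_{f,b}(v) - \mathrm{Poiss}(v)|$
  against the Poisson with the bin's empirical mean, aggregated as
  $L_f = \sum_b L_{f,b} n_b^+ / \sum_b n_b^+$;
* $Q_{f,b} = \ln(\langle v\rangle_b / \mathrm{Var}_b(v))$ — the log inverse
  Fano factor; zero-variance bins (family present at exactly equal copy
  number) inherit the family's maximum positive-variance $Q_{f,b}$, or the
  cap `q_cap = 5` when no bin has positive variance (flagged);
  $Q_f = \sum_b Q_{f,b} w_{f,b}$, the plain weighted sum (a normalized
  variant is available via `normalize_q`);
* occurrence $O_f$ (fraction of genomes carrying the family) and, given a
  transfer table, $H_f$ — the mean of $H_{f,g}/V_{f,g}$ over genomes where
  the family is present, the fraction of members scored as transfers.

Numerical conventions, each configurable: natural logarithm in $Q$; sums
over $v$ truncated at 450 (matching the analytic profiles, which are
evaluated in log space); population variance; histograms *include* the
$v = 0$ entries of genomes lacking the family (`include_zeros = TRUE` —
the model's Poisson prediction has mass at zero). The presence-only variant
(`include_zeros = FALSE`) matters when occurrence is far below 1: with zeros
included, partial occurrence mechanically inflates the variance and drags
$Q_f$ down, coupling $Q$ to $O$; presence-only keeps them decoupled, and the
test suite checks the $Q$–$O$ independence in that mode.

## Classification and downstream analyses

`classify_families()` labels families with $w_f < 0.38$ as undersampled
(0.38 is the published noise threshold, exposed as a default rather than
recalibrated — the calibration set is not reproducible here; note the
threshold keeps families *at or above* it, since higher $w_f$ means better
sampling), then splits on $Q_f$: overdispersed ($Q_f < -0.43$), peaked
($Q_f > 1$), Poisson-like otherwise; boundary equality goes to Poisson-like
since the thresholds are strict inequalities.

Downstream:

* `fisher_exact_2x2()` — hand-rolled two-sided Fisher exact test (sum of
  hypergeometric probabilities no larger than the observed table's, with a
  $1 + 10^{-7}$ tie guard; sample odds ratio $ad/bc$);
  `category_enrichment()` runs one test per (category, class) pair on the
  classified families, reporting raw p-values at $\alpha = 0.01$ plus a
  Benjamini–Hochberg column (no correction is applied by default);
* `plasmid_enrichment_score()` — log-ratio of a family's share of plasmid
  domains to its background share, pseudocount 0.5 by default;
* `class_restricted_distance()` — genome–genome Jaccard (presence/absence,
  default) or Bray–Curtis (counts) distances restricted to one class's
  families, with `spearman_distance_correlation()` against a reference
  (e.g. 16S-derived) distance matrix. Genomes whose restricted profile is
  empty sit at distance 1 from non-empty genomes and 0 from one another.

## The synthetic ensemble generator

`generate_ensemble(ensemble_spec())` emulates the statistical structure the
analysis assumes, with planted ground truth for testability. Defaults (the
reference conditions used by the test suite): 500 genomes in 4 clades;
100 families per class; Poisson families with $\lambda \sim U[5, 50]$;
overdispersed families as negative binomials with variance/mean 10
(equivalently $1 + p_d/p_h$); peaked families at constant copy number
$k \in \{3..8\}$ with $\pm 1$ noise at rate $\varepsilon = 0.1$ per
direction (noise variance $2\varepsilon$ — the paper-free generative choice
for sub-Poissonian profiles, which real data only exhibit); multiplicative
genome-size factors log-uniform on $[0.7, 1.4]$, wide enough to exercise
binning while keeping copy numbers realistic. Peaked families are the only
class whose *presence* carries phylogenetic signal: each is tied to one
clade in which genomes lack it with probability 0.1, chosen so that the
zero-inflation still leaves the planted $Q_f$ above the peaked threshold at
the largest $k$. Companion generators plant class-graded transfer tables
($H_{f,g} \sim \mathrm{Bin}(V_{f,g}, h_{\mathrm{class}})$ with defaults
0.4 / 0.3 / 0.02 for Poisson-like / overdispersed / peaked), class-associated
functional categories (default: metabolism at 3× relative risk in the
Poisson class), and a clade-block reference distance matrix.

What the generator does *not* emulate: family-size power laws and genome-size
scaling of functional categories, inter-family correlations, strain-level
structure, annotation errors in transfer scoring. Passing the round-trip
tests therefore shows the statistics recover *planted* structure of the
assumed form, not that real data satisfy the model.

```{r roundtrip, eval = FALSE}
sim <- generate_ensemble(ensemble_spec(), seed = 1)
fs <- family_stats(sim$counts,
                   transfers = generate_transfer_table(sim$counts, sim$truth))
table(planted = sim$truth$families$class,
      recovered = classify_families(fs)$class)
```

## The pipeline

`run_pipeline()` wires the stages over TSV inputs (families in rows,
explicit headers — the data are plain count tables, no richer format is
warranted): per-family statistics, labels, the $H_f$-vs-$Q_f$ binned trend,
category enrichment, plasmid scores, and class-restricted distance
summaries, plus a manifest (effective parameters and input checksums) that
makes a run reproducible and lets an unchanged rerun skip recomputation.
`read_pipeline_config()` parses a flat `key = value` file. The package is
driven from R; the functions and this vignette are its interface.

## Problem sizes and runtimes

The test suite and the acceptance script run stochastic checks at the sizes
the predictions refer to: $N = 1000$ species for the stationary profiles
(1500 sweeps for the Poisson regime, $10^4$ sweeps for the
duplication-dominated regime, pooled over 5–24 replicates), $N = 2000$ for
relaxation fits, and 500-genome / 300-family ensembles for the end-to-end
recovery. The whole suite completes in about two minutes on one CPU; the
acceptance script in under a minute.

## Known limitations

* No inference of $(p_h, p_d)$ from data is attempted; the statistics
  classify regimes, they do not estimate rates (in the Poisson regime $Q_f$
  is insensitive to $p_h$, and in the grazing limit only $p_d/p_h$ is
  identifiable; skewness-based estimates are too noisy in practice).
* The analytic relaxation-time expression is a kinetic-equation
  normalization; see the time-scale note above.
* The genome-size model variant is not implemented; size heterogeneity is
  handled on the data side by binning.
* Whether genes gained in a collision can be duplicated or lost within the
  same collision is unspecified in the model description; the simultaneous
  pre-collision-state update used here excludes it.
* With `include_zeros = TRUE` (the default) the $Q_f$ of families with low
  occurrence conflates absence with overdispersion; use the presence-only
  mode when occurrence varies strongly.
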