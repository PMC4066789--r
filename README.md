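# famfluct

Cross-species **gene-family abundance fluctuations** as a window on
horizontal gene transfer (HGT) dynamics in prokaryotes.

Bacterial genomes reshape their gene repertoires mainly by horizontal
transfer, duplication and loss. Beyond presence/absence, each domain family
*f* carries an *abundance profile*: the histogram of its copy number
V<sub>f,g</sub> across genomes *g*. `famfluct` is for comparative genomicists
who want to measure these profiles, classify families by them, and interpret
the classes through a minimal stochastic model — without needing the original
large-scale annotation databases, thanks to a fully synthetic, planted-truth
data generator.

## The model and the statistics

In the **collisional model**, N species genomes meet pairwise; in a collision
each partner gains the other's family members by Bernoulli trials with
probability p<sub>h</sub> per gene, while its own members are exclusively
lost (p<sub>l</sub>) or duplicated (p<sub>d</sub>). One sweep is N
collisions. The balance p<sub>h</sub> + p<sub>d</sub> = p<sub>l</sub>
conserves the mean abundance λ, and the mean-field steady state is:

* Poisson(λ) when p<sub>d</sub> = 0 — a parameter-free prediction;
* overdispersed otherwise, with
  Var(V) = λ (1 + p<sub>d</sub>/(p<sub>h</sub>(1 − p<sub>h</sub>)));
* a negative binomial of mean λ and variance
  λ (p<sub>d</sub> + p<sub>h</sub>)/p<sub>h</sub> in the grazing-collision
  limit (p<sub>d</sub>, p<sub>h</sub> → 0 at fixed ratio).

On the data side, statistics are computed in sliding genome-size bins
(width 390 domains): the sampling weight
w<sub>f</sub> = Σ<sub>b</sub> n<sub>b</sub> n<sub>b</sub><sup>+</sup> / Σ<sub>b</sub> n<sub>b</sub>²,
the L1 distance L<sub>f</sub> of the abundance histogram to the
equal-mean Poisson, the log inverse Fano factor
Q<sub>f</sub> = Σ<sub>b</sub> w<sub>f,b</sub> ln(⟨v⟩<sub>b</sub>/Var<sub>b</sub>(v)),
the occurrence O<sub>f</sub>, and the transfer fraction
H<sub>f</sub> = mean over genomes of H<sub>f,g</sub>/V<sub>f,g</sub>.
Families with w<sub>f</sub> ≥ 0.38 are classified as **overdispersed**
(Q<sub>f</sub> < −0.43, transfer *and* duplication), **Poisson-like**
(−0.43 < Q<sub>f</sub> < 1, transfer-dominated) or **peaked**
(Q<sub>f</sub> > 1, abundance-constrained), with Fisher-exact functional
enrichment, plasmid log-ratio scores and class-restricted genome distances
downstream.

## Worked example

Simulate the duplication-dominated regime and check it against the
mean-field prediction, then run the full analysis on a synthetic ensemble:

```r
library(famfluct)

p <- collision_params(p_h = 0.001, p_d = 0.009, N = 1000)
p
#> Collisional model parameters
#>   N   = 1000 species
#>   p_h = 0.001 (horizontal gain)
#>   p_d = 0.009 (duplication)
#>   p_l = 0.01 (loss; balances p_h + p_d)

se <- stationary_ensemble(p, init = 30, n_sweeps = 4000, burn_in = 1500,
                          snapshot_every = 250, n_reps = 4, seed = 7)
c(mean = se$mean, fano = se$fano)
#> stationary mean = 30.48, Fano factor = 9.99 (mean-field: 10.01)
l1_to_profile(se$values, grazing_limit_profile(30, 0.001, 0.009))
#> 0.018
```

The Fano factor (variance/mean) lands on the mean-field value
1 + p<sub>d</sub>/(p<sub>h</sub>(1 − p<sub>h</sub>)) ≈ 10.01, and the pooled
stationary histogram sits within L1/2 ≈ 0.02 of the grazing-limit negative
binomial.

```r
sim <- generate_ensemble(ensemble_spec(), seed = 1)   # 500 genomes, 3 x 100 families
tra <- generate_transfer_table(sim$counts, sim$truth, seed = 2)
fs  <- family_stats(sim$counts, transfers = tra)
fs
#> Family abundance-fluctuation statistics: 300 families x 500 genomes
#> 45 genome-size bins (width 390, step 100), 11-65 genomes each; 3 dropped (< 10)
#> First families:
#>   family_id w     L       Q O O_count     H zero_var
#> 1     F0001 1 0.313 -0.0160 1     500 0.399    FALSE
#> 2     F0002 1 0.310 -0.0388 1     500 0.399    FALSE
#> ...

lab <- classify_families(fs)
table(planted = sim$truth$families$class, recovered = lab$class)
#>                recovered
#> planted         overdispersed poisson_like peaked undersampled
#>   overdispersed           100            0      0            0
#>   peaked                    0            0    100            0
#>   poisson                   0          100      0            0

enr <- category_enrichment(lab, generate_category_annotations(sim$truth, seed = 3))
subset(enr, significant, select = c(category, class, odds_ratio, p_value, direction))
#>      category         class odds_ratio  p_value direction
#> 13 metabolism overdispersed      0.274 2.72e-04     under
#> 14 metabolism  poisson_like      5.394 1.75e-08      over
```

Every planted class is recovered from the abundance fluctuations alone, and
the planted metabolism association with Poisson-like families is detected at
P < 0.01. `run_pipeline()` performs the same stages over TSV inputs and
writes per-family statistics, labels, enrichment tables, plasmid scores,
distance summaries and a reproducibility manifest.

See the methods vignette
(`vignettes/family-abundance-fluctuations.Rmd`) for the model assumptions,
estimator choices, numerical conventions and known limitations.

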