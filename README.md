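# recne

Inference of **recent effective population size trajectories** (up to
~125 generations before present) from either of two haplotype-sharing
signals:

* the **length spectrum of IBD segments** called by an external detector
  (RefinedIBD/HapIBD-style files), or
* the **decay of long-range linkage disequilibrium (LD)** computed
  directly from unphased genotypes — including low-coverage,
  pseudo-haploid ancient-DNA panels with per-sample age ranges.

The package is aimed at population geneticists who have a SNP panel or an
IBD call set for a single population and want a regularised, uncertainty-
quantified $N_e(t)$ without phasing (LD mode) or with ground-truth IBD
(IBD mode).

## Model in brief

$N_e(t)$ is piecewise exponential on an adaptive grid over $(0, 125]$
generations and constant earlier.  With pair-coalescence probabilities
$q(g) = N_e(g)^{-1}\prod_{u<g}(1 - N_e(u)^{-1})$, the observables are:

* IBD counts per chromosome arm $i$ and 0.5 cM length bin $b$, Poisson
  with mean $\mu_b L_i$, where
  $\mu_b = \sum_g q(g)\,2g\,(e^{-2gu_{lo}} - e^{-2gu_{hi}})$ per
  haplotype pair per Morgan, overdispersion absorbed by quasi-likelihood
  factors $\phi_b^2$;
* binned mean $R^2$ statistics, Normal with mean
  $p_{IBD}(u) + (1 - p_{IBD}(u))\,\beta(n)$, where
  $p_{IBD}(u) = \sum_g q(g) e^{-2gu}$ and $\beta(n)$ is the exact
  finite-sample baseline of the unbiased-style $R^2$ estimator
  $[(\sum_i G_{i,x}G_{i,y})^2 - \sum_i G_{i,x}^2 G_{i,y}^2]/(s(s-1))$.

Fitting maximises a power likelihood $\prod_{i,b} P(Y_{i,b})^c$ times a
smoothness prior $\exp(-\lambda \sum_k (\Delta_k \log N_e)^2)$; $c$ and
$\lambda$ tune themselves (residual autocorrelation; conservative
region-held-out cross-validation).  Confidence bands come from 100
chromosome-arm bootstrap resamplings (2.5/25/75/97.5 percentiles).
Quality control drops outlier arms (6-SD and median-crossing rules for
LD; two-pass $\chi^2$ deviance test, $\alpha = 10^{-12}$, for IBD) and a
cross-chromosome LD test flags admixture-driven LD.

A segment-level coalescent simulator ships with the package — it
generates all test fixtures and doubles as the Monte-Carlo oracle for
every closed form above.  See the methods vignette
(`vignettes/recne-methods.Rmd`) for assumptions, tuning parameters and
limitations.

## Worked example

Simulate LD summaries for a population that crashed from 200,000 to
2,000 haploids at generation 25 and recovered to 20,000 by generation 50
("bottleneck" scenario; 100 diploids, 20 chromosome arms), then fit:

```r
library(recne)
ld  <- simulate_ld_summaries(scenario("bottleneck"), 100,
                             synthetic_genome(20, 18), seed = 42)
fit <- infer_ne_ld(ld, config = fit_config(seed = 42, n_bootstrap = 50))
fit$quantiles[c(1, 10, 25, 50, 100), ]
```

```
region filter: kept 20 of 20 regions
MAP fit: c = 1, lambda = 10, objective = 553.398
bootstrap: 50 replicates, 0 failures
    generation ne_map  q2.5   q25   q75 q97.5
1            1  24194 17906 22387 26753 33260
10          10  18028 14050 16684 19644 25040
25          25   5321  4030  4977  5735  6452
50          50   7780  6742  7344  8069  9037
100        100  16892 14536 15777 17356 19705
```

Columns are the MAP haploid size per generation with 95% (`q2.5`,
`q97.5`) and 50% (`q25`, `q75`) bootstrap bands.  The fit localises the
crash correctly — the trajectory bottoms out at generation 25 — while the
smoothness prior, as intended, pulls the trough depth and the recovery
toward flatness when 20 arms of LD carry limited information
(`rmsle(fit$map_model, scenario("bottleneck"))` ≈ 0.79 over the first 50
generations).  IBD mode (`infer_ne_ibd()`) resolves the same bottleneck
more sharply; the two modes cross-validate each other.

A thin command-line wrapper is installed at `exec/recne`:

```sh
recne simulate --scenario constant --n 100 --arms 20 --morgans 18 --seed 1 --out sim
recne ld --ld-summaries sim.ld.tsv --out fit --seed 1
recne ibd --ibd calls.ibd --map map.tsv --out fit_ibd
```

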