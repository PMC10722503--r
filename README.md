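# depauperon

Most macroevolutionary attention goes to radiations — clades with far more
species than expected.  The mirror image, *depauperons* (lineages with
unusually **low** species richness), is just as informative and much less
studied.  This package implements a topology-free way to find both: given
only each family's crown age and standing species richness, it asks whether
that richness is plausible under a constant-rate birth–death process fitted
to all families of the same geological interval, and classifies each family
as species-**poor**, as-**predicted**, or species-**rich**.  It is aimed at
plant macroevolution researchers (the design target is the ~432 angiosperm
families with ages from five calibrated phylogenies), but nothing in it is
angiosperm-specific.

## The model

A clade originating at time `t` that survives to the present under a
birth–death process with speciation rate λ, extinction rate μ
(net diversification r = λ − μ, extinction fraction ε = μ/λ) has a
geometric number of extant species:

    P(n) = (1 − β_t) β_t^(n−1),   β_t = (e^{rt} − 1) / (e^{rt} − ε)

Families with ages `t_i` and richness `n_i` therefore give the
log-likelihood  Σ_i [ ln(1 − β_i) + (n_i − 1) ln β_i ],  which is maximized
over an (r, λ) grid.  Two uncertainty systems are combined: the
profile-likelihood region (grid points within one log-unit of the maximum)
and the stochastic clade-size bounds

    k_upper = ln(0.025)/ln β + 1,   k_lower = ln(0.975)/ln β + 1.

A family is classified against the widest interval
`[min k_lower, max k_upper]` obtained over the whole profile region at its
age.  Per-dataset labels are merged by strict (5/5) and majority (4/5)
consensus.  Downstream, the package provides the association battery used
with such classifications (Pearson χ² with Haberman adjusted residuals,
Kruskal–Wallis + Dunn post-hoc under a global FDR, pairwise
Kolmogorov–Smirnov), occurrence-record cleaning, per-family diversification
rates on a 1° global grid, realm/biome range summaries, and a
synthetic-data generator that emulates every input with known truth.

## Worked example

```r
library(depauperon)
set.seed(42)

# 300 clades drawn from the model at r = 0.05, eps = 0.9
t    <- runif(300, 10, 120)
beta <- bd_beta(0.05, 0.9, t)
n    <- pmax(1, ceiling(log1p(-runif(300)) / log(beta)))

fit <- grid_mle(n, t, grid = grid_spec(r_step = 1e-3, lam_max = 10, lam_step = 0.05))
fit
#> birth-death grid MLE (300 clades): r = 0.0491, lambda = 0.5, eps = 0.9018
#>   max log-likelihood -1909.1884; 9 grid points within 1 log unit(s)
#>  param  lower  upper
#>      r 0.0471 0.0521
#>    lam 0.4500 0.5500
#>     mu 0.3979 0.5029
```

The fit recovers the generating rates (r̂ = 0.0491 vs 0.05, ε̂ = 0.90) and
the profile interval on r spans 0.047–0.052.  Classifying the same clades
against the fit:

```r
rec <- data.frame(family = sprintf("Fam%03d", 1:300), richness = n, age = t,
                  dataset = "demo", age_source = "observed")
calls <- classify_richness(rec, fit)
table(calls$category)
#>      high       low predicted
#>         9         8       283
```

283/300 ≈ 94% of model-drawn clades fall inside the bounds — the expected
behaviour of a 95% stochastic interval.  A full multi-dataset study
(simulate → fit per dataset × interval → classify → consensus → trait and
geography stages) is one call:

```r
res <- run_pipeline(pipeline_config(synthetic = sim_config(seed = 1)))
res$counts          # strict-consensus category counts and percentages
res$manifest        # config hash, stage record counts
```

See the vignette (`vignettes/clade-richness-classification.Rmd`) for the
model details, the generator's design, and the numerical choices.

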