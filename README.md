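# shannonpop

Bias-aware estimation of the Shannon diversity index for population
genetics, with a coalescent simulation framework that quantifies how badly
each estimator misbehaves at realistic sample sizes.

The plug-in ("maximum likelihood") Shannon index
*H* = −Σᵢ pᵢ ln pᵢ over allele frequencies is negatively biased in small
samples: rare alleles go unsampled and the sampled frequencies inflate.
`shannonpop` implements the plug-in estimate (`h_mle`) together with three
bias-corrected estimators —

* `h_zahl` — Zahl's jackknife, *n·Ĥ − (n−1)·mean(leave-one-out Ĥ)*;
* `h_chao_shen` — the coverage-adjusted Horvitz–Thompson estimator using
  Good–Turing coverage *Ĉ = 1 − f₁/n* (undefined when every allele is a
  singleton; that failure is reported as a missing value, not an error);
* `h_chao2013` — the Chao et al. (2013) harmonic-sum estimator with a
  singleton/doubleton tail correction —

plus Nei's gene diversity (`gene_diversity`), all on simple allele-count
vectors or GENEPOP files. Around the estimators sits the machinery of a full
simulation study: a compiled Kingman coalescent for microsatellite loci
under a bounded stepwise mutation model and piecewise-constant demography
(`simulate_population`, `default_scenarios`: a constant population of
10,000 diploids and three 20-generation bottlenecks of 500/50/20), and a
resampling experiment (`run_experiment`) that measures each estimator's
relative bias *rB = (Ĥ−H)/H*, mean relative squared error
*MRSE = mean((Ĥᵢ−H)²/H)* and sampling SD against whole-population parametric
values, at 5/20/80/200 sampled genotypes.

## Worked example

Estimate all metrics on one allele-count vector (two singletons and a
doubleton):

```r
library(shannonpop)
estimate_all(c(1, 1, 2))
#>   metric locus    value
#> 1  H_MLE       1.039721
#> 2    H_Z       1.556193
#> 3   H_CS       1.763240
#> 4 H_Chao       1.587460
#> 5     Hs       0.625000
```

Simulate a constant-size population at four fast-mutating loci, then watch
the plug-in estimator collapse on a 5-genotype sample while the jackknife
holds:

```r
set.seed(1)
pop <- simulate_population(default_scenarios()$P_C,
                           default_loci()[c(6, 12, 18, 24), ],
                           10000, population = "P_C")
ref <- parametric_reference(pop)
subset(ref, locus == "mean")
#>  population replicate locus metric     value sample_size
#>         P_C         1  mean  H_MLE 2.1631076  parametric
#>         P_C         1  mean    H_Z 2.1634079  parametric
#>         P_C         1  mean   H_CS 2.1631076  parametric
#>         P_C         1  mean H_Chao 2.1634077  parametric
#>         P_C         1  mean     Hs 0.8573404  parametric

set.seed(2)
sub <- subsample(pop, 5)
mean(sapply(pop$loci, function(l) h_mle(allele_counts(sub, l))))
#> [1] 1.708824   # rB = -0.21 against the parametric 2.1631
mean(sapply(pop$loci, function(l) h_zahl(allele_counts(sub, l))))
#> [1] 2.180360   # rB = +0.0078
```

The same five genotypes cost the plug-in estimator a fifth of the true
diversity; the jackknife recovers it to within one percent.

Whole experiments are driven by a configuration object or YAML file and
write tidy CSV records (`references.csv`, `bias.csv`, `mrse.csv`, `sd.csv`,
`failures.csv`), summary tables and a JSON run manifest:

```r
cfg <- sim_config(preset = "scaled") # full design, 100 replicates
res <- run_experiment(cfg, out_dir = "run1", progress = TRUE)
res$tables$table4 # min/median/max relative bias by sample size and metric
```

A thin command-line front end with the same capabilities ships in
`inst/cli/shannonpop` (subcommands `estimate`, `experiment`, `summarize`;
`experiment --dry-run` prints the planned design size — 192,096,000
estimation events per metric for the full preset — without simulating).

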