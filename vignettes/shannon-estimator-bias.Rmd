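---
title: "Sample-size bias of Shannon diversity estimators on multiallelic loci"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Sample-size bias of Shannon diversity estimators on multiallelic loci}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(shannonpop)
```

## The problem

The Shannon diversity index of a locus,
$H = -\sum_i p_i \ln p_i$ over allele frequencies $p_i$ (in nats throughout
this package), is a popular measure of genetic variation because it weighs
rare alleles more heavily than heterozygosity does. Its plug-in estimate from
a sample, however, is negatively biased: a small sample misses rare alleles
and inflates the frequencies of the alleles it did catch. Population
geneticists routinely work with 5-20 genotypes per population, exactly the
regime where the bias is worst.

`shannonpop` provides four estimators of $H$ on allele-count data, a
coalescent simulator for bounded stepwise-mutation (microsatellite) loci
under bottleneck demographies, and a resampling experiment that measures each
estimator's relative bias and error as a function of sample size — so the
practical question "which estimator should I report at my sample size?" can
be answered by simulation rather than convention.

## Estimators

All estimators consume a vector of positive allele counts $x_i$ with
$n = \sum_i x_i$ gene copies, $\hat p_i = x_i/n$, and $f_1$, $f_2$ the
numbers of alleles seen exactly once and twice:

* **Plug-in (`h_mle`)**: $\hat H = -\sum_i \hat p_i \ln \hat p_i$.
* **Zahl's jackknife (`h_zahl`)**:
  $n\hat H - \frac{n-1}{n}\sum_i x_i \hat H_{(-i)}$, where $\hat H_{(-i)}$ is
  the plug-in estimate after deleting one copy of allele $i$. The
  implementation groups the $n$ leave-one-out terms by allele (an $O(k^2)$
  computation) but is exactly equal to the literal $n$-fold recomputation;
  the test suite enforces equality to $10^{-12}$ for every counts vector
  with $n \le 12$.
* **Chao–Shen (`h_chao_shen`)**: Good–Turing coverage
  $\hat C = 1 - f_1/n$ deflates the frequencies,
  $\tilde p_i = \hat C \hat p_i$, and a Horvitz–Thompson correction
  reweights each term:
  $\sum_i \frac{-\tilde p_i \ln \tilde p_i}{1 - (1-\tilde p_i)^n}$.
  When *every* allele is a singleton ($f_1 = n$) the coverage is zero and
  the estimator is undefined. This is a first-class failure mode, not an
  exception: `h_chao_shen()` returns `NA`, batch estimation records the
  missing value and carries on, and the experiment counts the failures.
  Small, highly diverse samples are where it strikes.
* **Chao et al. 2013 (`h_chao2013`)**: the harmonic-sum estimator
  $\sum_i \frac{x_i}{n}\sum_{k=x_i}^{n-1}\frac 1 k$ plus a singleton tail
  correction parameterised by
  $A = 2f_2 / ((n-1)f_1 + 2f_2)$ (with the $f_2 = 0$ and $f_1 = 0$ special
  cases).
* **Nei's gene diversity (`gene_diversity`)**: $1 - \sum_i \hat p_i^2$, the
  conventional reference measure.

```{r estimators}
x <- c(1, 1, 2) # two singletons and a doubleton, n = 4
c(H_MLE = h_mle(x), H_Z = h_zahl(x), H_CS = h_chao_shen(x),
  H_Chao = h_chao2013(x), Hs = gene_diversity(x))
```

### Numerical notes

* $0 \ln 0$ is taken as 0 wherever a probability term vanishes.
* The inner sums of `h_chao2013` use cumulative harmonic numbers
  ($O(n + k)$ rather than $O(nk)$), so whole-population samples of 20,000
  gene copies are cheap.
* The tail correction of `h_chao2013` contains the difference
  $-\ln A - \sum_{r=1}^{n-1}(1-A)^r/r$, which cancels catastrophically when
  $(1-A)^{n-1}$ is tiny. The implementation switches to the equivalent
  convergent series $\sum_{s\ge1}(1-A)^s/(s+n-1)$ once
  $(n-1)\,|\ln(1-A)| \ge 30$; at the switch point both forms agree to well
  beyond the accuracy that matters downstream.

## The simulator

Microsatellite loci are simulated one at a time with a Kingman coalescent
under piecewise-constant diploid population size: with $j$ lineages and
size $N$, coalescence waiting times are exponential with total rate
$j(j-1)/(4N)$ per generation, bounded at epoch boundaries. Mutations fall on
branches as a Poisson process at rate $\mu$ per generation and move the
allele state $\pm 1$ with equal probability inside a window of `k_max`
states; a step that would leave the window is discarded (the state does not
change). The root state is the window centre `floor(k_max / 2)`, which makes
low-mutation runs reproducible and lets the cap bind symmetrically. Diploid
genotypes are formed by pairing consecutive tips — coalescent tips are
exchangeable, so this is a random union of gametes.

Design choices worth knowing about:

* **Coalescent, not forward simulation.** The experiment samples whole
  populations of 10,000 diploids; a coalescent on 20,000 tips takes
  milliseconds in the compiled core, where a forward simulator would burn
  minutes per replicate. The continuous-time approximation is kept even
  through 20-generation bottlenecks (epoch boundaries bound the waiting
  times); its error is small relative to replicate noise at this scale.
* **Boundary rule.** Whether an out-of-window mutation is discarded or
  reflected is exposed as `boundary = c("discard", "reflect")` on the
  simulator. Empirically the choice moves scenario-mean diversity by less
  than 0.01, so nothing downstream hinges on it; `discard` is the default.
* **Pure single-step mutation.** Real microsatellites sometimes mutate by
  several repeat units at once (a geometric "multistep" component). The
  generator deliberately uses the single-step model with the design's
  printed rates; see *Limitations*.
* **Seed discipline.** Every (replicate, scenario, locus) triple gets its own
  RNG stream derived from the master seed by hashing, so replicates are
  reproducible individually, independent of execution order, and two runs
  that share a master seed simulate literally identical populations even if
  they request different sample sizes.

The four demographic scenarios of `default_scenarios()` are a constant
control `P_C` (N = 10,000 diploids) and three bottlenecks `P_500`, `P_50`,
`P_20`: backward from sampling, 20 generations at 10,000 (the recovery), 20
generations at 500 / 50 / 20 (the bottleneck), and 10,000 before that. The
24 loci of `default_loci()` cross mutation rates
$\{10^{-4}, 2\times10^{-4}, 5\times10^{-4}, 10^{-3}\}$ per gene copy per
generation with allele-count caps $\{3, 6, 9, 12, 15, 20\}$.

```{r sim}
set.seed(1)
pop <- simulate_population(default_scenarios()$P_20, default_loci()[1:4, ],
                           n_individuals = 200, population = "demo")
sapply(pop$loci, function(l) gene_diversity(allele_counts(pop, l)))
```

## The experiment

For each replicate and scenario the whole population is simulated and the
**parametric** value of every metric is computed per locus and as the mean
over loci — the ground truth $H$. For each sample size $N_s$ (defaults 5,
20, 80, 200 genotypes) the experiment draws `n_resamples` (default 500)
independent subsamples of whole individuals without replacement, estimates
every metric per locus and as the mean over loci, and reduces them to:

* **relative bias** $rB = (\hat H - H)/H$, computed once per
  metric/population/sample size from the *first* resample (deterministic
  and independent of the later draws — the design calls for a single draw
  per cell and does not name which one);
* **mean relative squared error**
  $\mathrm{MRSE} = \frac1m \sum_{i=1}^{m} (\hat H_i - H)^2 / H$ over the
  $m$ non-missing resample estimates (squared deviations divided by $H$,
  not $H^2$ — the convention is kept exactly as published), per locus and
  for the mean over loci;
* **SD**, the standard deviation of the mean-over-loci estimates across the
  resamples.

A mean-over-loci value of the coverage-adjusted estimator is missing
whenever any locus failed, so its failures propagate visibly instead of
silently truncating the mean. Resamples are drawn independently per sample
size (the alternative — drawing once and reusing across sizes — would
correlate the size series for no benefit).

SD distributions are compared between metrics by drawing `n_pairs` (default
100,000) random pairs, one value from each distribution; the reported $p$ is
the fraction of pairs ordered against the observed difference of means,
floored at $1/\texttt{n\_pairs}$. Ties count against rejection — two
identical distributions give $p = 1$ — and the test is one-sided in the
direction of the observed means. These tie/sidedness rules are this
package's own, as is the convention that summary Table 3 excludes a
Chao–Shen cell whose resampling was incomplete in any replicate.

The full design (`sim_config(preset = "paper")`) evaluates each metric
$24 \times 4 \times (4 \times 500 + 1) \times 1000 = 192{,}096{,}000$ times;
`count_estimation_events()` and the command front end's dry run report this
without simulating. The `"scaled"` preset keeps the identical populations,
loci and sampling scheme at 100 replicates, which is what the test suite and
the acceptance script run: medians and means of $rB$ and SD are stable at
that scale (a few minutes on one CPU), and every summary in this vignette or
the README was produced by one of those runs.

## What the generator does and does not emulate

The simulator reproduces the features that drive estimator bias: realistic
allele-frequency spectra under mutation-drift balance, allele-count caps,
loss of rare alleles through bottlenecks, and whole-population ground truth.
It does not emulate genotyping error, null alleles, missing data (the
GENEPOP reader handles missing codes, the simulator never emits them),
linkage, selection, or migration. Passing tests therefore say: *given clean
genotypes from an equilibrium or bottlenecked population, the estimators
rank and err as described*; they do not certify behaviour under genotyping
artefacts.

## Limitations

* **Absolute diversity levels depend on mutation-model details.** With the
  printed per-copy rates and a pure single-step model, the constant-size
  scenario settles at a mean-over-loci $H_{MLE}$ around 1.56 (Hs ≈ 0.73);
  reported values for the equivalent fastsimcoal2 setup are ~7% higher,
  consistent with extra mutational variance from settings that tool does not
  print (e.g. a non-zero multistep component). The discrepancy shifts
  high-diversity scenario levels only: bottleneck-scenario levels, scenario
  orderings, bias profiles, SD means and failure patterns all agree. The
  generator's parameters are fixed by the design, not calibrated to outputs,
  so this gap is documented rather than absorbed.
* The Chao–Shen failure condition implemented here (zero coverage,
  $f_1 = n$) is the mathematically forced one; other implementations fail
  more often for incidental reasons (nested richness estimation), so failure
  *counts* are comparable only qualitatively.
* The coalescent treats the 20-generation bottlenecks in continuous time;
  with bottleneck sizes of 20-500 diploids and 20,000 sampled copies this
  slightly smooths the collapse of lineages relative to a discrete
  Wright-Fisher generation scheme. The effect on surviving-lineage counts
  (what diversity actually depends on) is second-order.
* GLM-based downstream analysis of MRSE (gamma/log link, information
  criteria, post-hoc contrasts) is intentionally out of scope: the
  experiment exports a tidy per-locus table (`mrse.csv` with columns
  `metric, population, sample_size, replicate, locus, He_locus, mrse, m`)
  that any statistics environment can model directly.
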