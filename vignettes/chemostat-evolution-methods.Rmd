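---
title: "Methods: analyzing adaptive evolution in nitrogen-limited chemostats"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: analyzing adaptive evolution in nitrogen-limited chemostats}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
set.seed(1)
library(chemevolve)
```

This vignette explains the statistical models behind `chemevolve`, the
assumptions each one makes, and the reasoning behind the package's default
parameter choices. The package is built around the analysis of long-term
selection experiments in ammonium-limited continuous culture: an asexual
yeast population adapts for hundreds of generations, beneficial mutations in
a small nitrogen-regulatory gene network sweep and interfere with one
another, and the experimenter observes the process through allele-frequency
time courses, pairwise competition assays, pooled sequencing, and
expression arrays.

## The chemostat clock

In a chemostat at steady state the population's specific growth rate equals
the dilution rate $D$, so the doubling (generation) time is $\ln 2 / D$. At
the default $D = 0.12\,\mathrm{hr}^{-1}$ this is

```{r}
doubling_time(0.12)
```

hours, and a 250-generation selection takes

```{r}
selection_duration_days(250, 0.12)
```

days — about two months of wall-clock time. These closed forms are used
throughout to convert between generations and days.

## The simulator: a genotype tree under Wright–Fisher resampling

`simulate_chemostat_evolution()` tracks whole genotypes, not independent
loci: every mutation founds a new node in a genotype tree, and a genotype's
frequency is resampled each generation by multinomial (Wright–Fisher)
sampling of $N$ individuals with Malthusian weights $e^{s}$.

Two modeling choices deserve justification:

* **Malthusian weights.** With fitness acting multiplicatively as $e^{s}$
  per generation, a mutant competing against a wild type follows the
  logistic closed form
  $x_t = x_0 e^{st} / (1 - x_0 + x_0 e^{st})$ in the deterministic limit,
  and the log abundance ratio $\ln(x_t / (1-x_t))$ is exactly linear in $t$
  with slope $s$. This makes the simulator consistent with the regression
  estimator below: the quantity the estimator recovers is the same $s$ the
  simulator consumes. The package reports relative fitness as $1 + s$,
  which agrees with $e^s$ to first order in the small-$s$ regime
  ($s \lesssim 0.25$) these experiments occupy.
* **Effective population size as a free parameter.** Chemostat censuses are
  enormous ($>10^9$ cells), but the effective size governing drift and the
  supply of *contending* beneficial mutations is far smaller and is not
  identifiable from the data the package models. The default
  $N = 10^5$ is a desk-scale choice that preserves the qualitative regime
  of interest — sweeps are near-deterministic once established, while new
  single-copy mutants are frequently lost to drift — at tractable cost.
  All conclusions drawn from simulations here are about the package's
  algorithms, not about absolute mutation-supply rates.

Scripted scenarios (`scheduled_mutations`) force specific mutations into
specific lineages at specific generations, which is how the bundled
clonal-interference demos are constructed. Scripted runs default to
deterministic propagation: a scheduled single mutant at frequency $1/N$
would be lost to drift in most stochastic runs, silently breaking the
script. Stochasticity then enters through the observation models —
Gaussian noise with a detection floor for Sanger-style allele-frequency
estimates, and binomial read sampling at a configurable depth (default
160×) for deep sequencing.

What the generator deliberately does **not** emulate: mutation-rate
heterogeneity along the genome, selection coefficients that change as the
environment coevolves, recombination (the populations are asexual), and
frequency-dependent interactions other than simple resource competition.
Epistasis can be injected explicitly via `epistasis_overrides`.

## Selection coefficients from competition assays

`estimate_selection_coefficient()` fits ordinary least squares of
$\ln(\text{evolved}/\text{reference})$ on time in generations. Under the
exponential model the log ratio is linear with slope $s$; the Student-$t$
interval with $n - 2$ degrees of freedom is honest when the residuals are
roughly independent Gaussian on the log scale, which holds for
count-derived ratios away from the floor where one strain becomes too rare
to count (such points are flagged by `competition_series()`, never silently
dropped). The default assay design — 1:5 starting ratio, samples every 2–3
generations over ~20 generations — gives the estimator enough leverage
that, at log-ratio noise of 0.1, the bias is below 0.01 and the 95% CI
covers at close to nominal rate (verified in the test suite on 1,000
simulated assays).

```{r}
ser <- simulate_competition(s_true = 0.25, noise_sd = 0.05, seed = 7)
estimate_selection_coefficient(ser)
```

## Lineage reconstruction

### Clustering trajectories

Mutations carried by the same genotype hitchhike together, so their
frequency trajectories are statistically indistinguishable.
`cluster_trajectories()` merges trajectories when **every** cross pair has
Pearson $r > 0.97$ and terminal deep-sequencing frequencies within 4%
(strict inequalities). The all-pairs criterion prevents chaining: two
dissimilar trajectories can never end up merged through an intermediate.
The terminal-frequency threshold defaults to 4%; a 5% variant is in
circulation for this procedure and is available through `max_final_diff`.
Within a cluster, mutations are ordered by their terminal deep-sequencing
frequencies: in an asexual lineage the earlier mutation is carried by every
cell carrying the later one, so it must be at least as frequent.

### Nesting clusters into a genotype tree

`infer_genotype_nesting()` reconstructs which lineages arose within which.
It is a greedy containment algorithm with three decisions worth recording:

1. **Visiting order is by time-averaged frequency, not peak frequency.**
   If lineage B arose inside lineage A, then A's frequency dominates B's at
   every timepoint; both the peak and the mean therefore respect the true
   nesting in noiseless data. But the margin at the peak can be a fraction
   of the noise standard deviation (two nested sweeps both near fixation
   differ by only the exclusive remainder of the parent), whereas the mean
   accumulates the margin across all timepoints. In simulations with two
   close nested sweeps, peak ordering inverted parent and child in roughly
   40% of noisy replicates; mean ordering is stable.
2. **Sibling headroom scales as $\mathrm{tol}\sqrt{k+1}$.** A candidate
   child fits under a parent only if the parent's frequency can hold the
   existing $k$ children plus the candidate. That comparison sums $k + 1$
   noisy frequencies, so its noise scales with $\sqrt{k+1}$; a fixed
   tolerance would spuriously reject children of crowded parents.
3. **Clusters that fit nowhere attach to the root.** A lineage whose
   containment checks all fail by a hair is reported as an independent
   lineage from the ancestor rather than aborting the reconstruction; the
   hard error is reserved for impossible data (frequency above $1 +
   \mathrm{tol}$).

With the default tolerance of 0.05 (the measurement noise floor of the
frequency assays), noiseless reconstructions of scripted nested sweeps are
exact, and with Gaussian noise of sd 0.02 the algorithm recovers about 98%
of true parent–child edges across replicates.

`to_muller_table()` converts the tree's cumulative frequencies into
exclusive genotype frequencies for Muller plots, clipping small negative
values and refusing to clip violations beyond the tolerance.

## Fitness landscapes and epistasis

For $k$ loci measured in all $2^k$ combinations,
`epistasis_terms()` applies the inclusion–exclusion (Möbius) transform on
the selection-coefficient scale:
$\varepsilon_S = \sum_{T \subseteq S} (-1)^{|S| - |T|} s_T$, with
$s_\emptyset = 0$. Singleton terms are the single-mutant effects; the
pairwise term for loci $\{i,j\}$ is the familiar
$s_{ij} - s_i - s_j$; the transform is exactly invertible
(`epistasis_to_fitness()`), which the test suite checks to $10^{-12}$.
Working on the $s$ scale (rather than $\log$ fitness) matches the scale on
which the competition estimator reports and on which additivity is the
natural null for small $s$.

`accessible_paths()` enumerates all $k!$ acquisition orders and calls a
step favored when the fitness difference along the corresponding hypercube
edge is significantly positive (one-sided $z$ on propagated standard
errors; point estimates when `alpha = NA`). The canonical three-locus
pattern — a trafficking-gene allele that is neutral alone, beneficial on
either single-mutant background, and deleterious on the double-mutant
background — leaves exactly the two orderings that place that allele
second accessible:

```{r}
land <- fitness_landscape(
  c("gat1", "mep2", "lst4"),
  data.frame(genotype = c("000", "100", "010", "001",
                          "110", "101", "011", "111"),
             s = c(0, 0.10, 0.12, 0.002, 0.25, 0.17, 0.18, 0.20),
             se = 0.005))
paths <- accessible_paths(land)
paths[paths$accessible, ]
```

`classify_pairwise_epistasis()` applies the standard taxonomy (none /
magnitude / sign / reciprocal sign) with two-sided $z$-tests, and
`export_dot()` renders the hypercube with favored edges solid and
disfavored edges dashed.

## Variant filtering and mutation-spectrum statistics

`filter_population_variants()` encodes the heuristics appropriate for
pooled sequencing of a heterogeneous population at ~160× depth, applied in
a fixed order with the first failing rule logged per call: ancestor
subtraction, population uniqueness, presence at both lenient and strict
base-quality tiers, caller $p \le 10^{-8}$, site depth at least half the
sample mean, and allele frequency at least 5%. The 5% floor matches the
binomial detection power at the operating point:

```{r}
detection_power(depth = 160, true_freq = 0.05, min_alt_reads = 4)
```

Spectrum statistics use exact binomial tests
(`coding_bias_test()`, `nonsynonymous_fraction_test()`), with the
two-sided minimal-likelihood convention of `stats::binom.test()` as the
default sidedness — the convention under which the canonical worked
examples (60 coding among 72 SNPs against a 0.72 coding fraction; 52
nonsynonymous among 72 against 0.79) reproduce their quoted p-values of
0.035 and 0.19. `expected_snp_burden()` defaults to the measured
spontaneous substitution rate for yeast of $3.3 \times 10^{-10}$ per site
per generation over a 12 Mb genome and 250 generations, giving an expected
burden of ~1 substitution per lineage — the benchmark against which an
observed mean of 4 SNPs per clone is elevated.

## Expression divergence and enrichment

`gene_set_divergence_test()` asks whether a gene set (canonically a
38-gene nitrogen-catabolite-repression regulon) is more perturbed than
random sets: the statistic is the mean $|\log_2|$ ratio over the set, and
the null is built by drawing equal-size sets without replacement from all
measured genes. The permutation p-value uses the add-one estimator
$(1 + \#\{\text{null} \ge \text{stat}\})/(n_{\mathrm{perm}} + 1)$ so a
finite run never reports $p = 0$; the plain fraction is available for
comparison against exhaustive enumeration. The test's type-I error at
nominal 0.05 is verified to lie in $[0.03, 0.07]$ under a null matrix.

`functional_enrichment()` is a one-tailed Fisher exact test per term with
Bonferroni correction over the terms actually tested. The counting rules
are explicit: unannotated hit genes are excluded first; loci with several
independent alleles contribute one count per allele; intergenic mutations
count toward both flanking genes (`map_mutations_to_genes()`); terms
annotated to fewer than 2 or more than 100 genes in the universe are
dropped before testing.

## The demo pipeline

`run_pipeline()` chains the stages on synthetic data — simulation,
fitness estimation, lineage reconstruction, landscape analysis, variant
filtering, enrichment — writing TSV/JSON/DOT outputs plus a manifest with
md5 checksums. Per-stage seeds are derived from the single configuration
seed, so a rerun with the same configuration is byte-identical, and
configurations round-trip through YAML or JSON
(`write_pipeline_config()`).

## Limitations

* The simulator's population size, mutation-rate defaults and scripted
  scenarios are desk-scale stand-ins chosen to exercise the analysis
  algorithms, not calibrated population-genetic models.
* Trajectory clustering assumes a shared sampling grid and cannot separate
  mutations that are genuinely co-swept but genetically independent; clone
  genotyping (`require_same_clone`, clone vetoes in nesting) is the only
  guard.
* The nesting algorithm is greedy; pathological landscapes of overlapping
  partial sweeps can defeat it, and its tolerance must reflect the real
  measurement noise.
* Epistasis decomposition requires a complete hypercube and treats the
  per-genotype standard errors as independent.
* `score_calls_binomial()` is a stand-in statistic for synthetic data, not
  a re-implementation of any published variant caller; real data should
  carry the upstream caller's p-values.
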