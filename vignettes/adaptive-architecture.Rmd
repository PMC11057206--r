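---
title: "Inferring adaptive architecture from the evolution of phenotypic variance"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Inferring adaptive architecture from the evolution of phenotypic variance}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(adaptarch)
```

## The question

When a population adapts to a new environment, is the response driven by a
handful of large-effect loci (an *oligogenic* architecture) or by many loci
of small effect (a *polygenic* one)? Allele-frequency data often cannot
tell: redundant polygenic responses leave weak, inconsistent signatures.
`adaptarch` implements an alternative read-out: the **temporal dynamics of
the phenotypic variance**. A trait adapting through few loci loses (or
transiently gains, then loses) phenotypic variance as those loci sweep;
a highly polygenic trait adapts through many small frequency shifts and its
variance stays close to the neutral expectation. Tracking the variance ratio

$$F = \sigma_x^2 / \sigma_1^2$$

(phenotypic variance at generation $x$ over the variance at generation 1)
across an evolve-and-resequence experiment therefore carries information
about the adaptive architecture.

The package provides, end to end on synthetic data:

1. a founder-haplotype and genetic-map generator (`generate_founder_haplotypes()`,
   `generate_genetic_map()`, `neutral_burnin()`);
2. trait architectures: gamma effect sizes standardized to mean $1/M$,
   a negative frequency–effect correlation, dominance, heritability
   (`trait_architecture()`, `build_module_architecture()`);
3. a diploid Wright–Fisher forward simulator with Poisson-crossover
   recombination and Gaussian (or multivariate Gaussian) stabilizing
   selection around a shifted optimum (`evolve()`);
4. variance-change statistics and ensemble summaries (`variance_ratio()`,
   `sample_variance_ratio()`, `trajectory_band()`);
5. the inference layer: a single-trait variance $F$-test against the
   neutral expectation, a group-level $t$-test, simulation-based power
   grids, a lower bound on the number of contributing loci, and a
   replicate-correlation permutation test;
6. an RNA-seq expression-variance stage: TMM-normalized natural-log CPM,
   per-gene variance change, jackknife confidence intervals, a partition of
   the squared coefficient of variation into technical and biological
   components, and the DE-versus-non-DE comparison.

## The simulation model

**Founders and maps.** Every simulation starts from a panel of founder
haplotypes (default 189, the size of a typical *Drosophila*
experimental-evolution founder panel). Per-locus allele frequencies are
drawn from a configurable site-frequency spectrum — default Beta(1, 3),
skewed toward rare variants as in a sample from a large natural
population — and realized by binomial sampling; panel loci are in linkage
equilibrium. The default genetic map is a synthetic stand-in: 5 Morgans
spread uniformly over 5 chromosome arms, roughly a Drosophila-like female
map (an empirical map can be loaded with `read_genetic_map()`).
Recombination uses Poisson-distributed crossovers without interference, so
distances convert to recombination fractions by the Haldane function;
chromosomes assort independently.

**Architectures.** A trait is controlled by $M$ loci ($M \in
\{5, 25, 50, 100, 200, 1000\}$ in the study grid). Effect-size magnitudes
are gamma draws with shape 0.5 / 2.5 / 100 (very unequal to nearly equal
effects), rescaled so their sample mean is exactly $1/M$ — this keeps the
expected genetic variance comparable across shapes. Magnitudes are then
permuted against the allele frequencies with a Gaussian-copula rank
construction so the Spearman correlation hits a target (default $-0.7$:
rare alleles carry large effects); the permutation preserves the effect
marginals exactly. Effect *signs* are flipped with probability 0.5 by
default: whether the original effects were all-positive is not determined
by the sources, and sign-symmetric effects avoid a degenerate directional
ancestral mean while leaving $|{\rm effect}|$ and the variance dynamics
unchanged. Dominance is additive ($d = 0.5$) by default, configurable
per locus.

**Heritability.** Each trait draws a narrow-sense heritability from
`sample_heritability()` — default Beta(3.2, 1.7), mean $\approx 0.65$. The
environmental variance is assigned at founding as
$\sigma_E^2 = V_{\rm anc}(1 - h^2)/h^2$ from the realized ancestral genetic
variance, so the generation-1 heritability equals the drawn $h^2$ exactly.
The Beta(3.2, 1.7) default was chosen once, *a priori*, so that the
expected neutral variance ratio after 100 generations at $N = 300$,
$1 - \bar{h^2}\,(1 - (1 - \tfrac{1}{2N})^{100}) \approx 0.9$, matches the
neutral reference the inference layer tests against; an empirical table of
heritabilities can be substituted via the `h2_sampler` argument.

**Selection.** Fitness is Gaussian in the phenotype $z$ with optimum
$z_0 = \bar{X}_{\rm anc} + a\sqrt{V_{\rm anc}}$ and width
$b\sqrt{V_{\rm anc}}$, anchored to the ancestral genetic variance captured
at generation 1 (no pre-shift equilibration: experimental populations are
typically phenotyped in the new environment from the start). $a = 1$ is a
mild shift, $a = 3$ a distant one; $b$ = 1.8 / 3.6 / 5.4 spans strong to
weak stabilizing selection. For modules of coregulated traits, fitness is
multivariate:
$\omega = \exp\!\big(-\tfrac12 \sum_i (z_i - z_0)^2 / (2 V_s)\big)$ with
$V_s = b\sqrt{V_{{\rm anc},i}}$. This exponent convention carries both a
$\tfrac12$ prefactor *and* a $2V_s$ denominator — flatter than a standard
Gaussian with variance $V_s$. It is implemented exactly as written because
it is the form the module analyses are defined with; set
`exponent_convention = "standard_gaussian"` in `fitness_regime()` for the
conventional form.

**Reproduction.** Monoecious Wright–Fisher: each of the $N$ offspring
draws two parents independently with probability proportional to fitness
(selfing allowed), and each gamete recombines the parent's two haplotypes.
Census size equals effective size; no de-novo mutations arise during the
experiment (they contribute little on a 100-generation timescale), so all
response comes from standing variation. `neutral_burnin()` adds recurrent
mutation and is used only to build ancestral populations for the modular
scenario; its reference configuration (N = 10,000, 20,000 generations,
5,000 loci at $r = 0.001$) is accepted as configuration, while package
defaults are scaled down — the mutation–drift equilibrium check in the test
suite runs at $N = 100$ for the same reason.

Because only the causal loci influence a trait and every trait evolves in
its own run, `evolve()` silently restricts the simulated population to the
architecture's loci (map positions preserved). This is exact, not an
approximation, and is what makes ensembles of thousands of runs cheap.

## The inference layer

**Single trait.** For one focal trait, the observed
$F_{\rm obs} = s_x^2/s_1^2$ is compared against the mean neutral ratio
$F_{\rm neutral}$ (about 0.9 at generation 100 for $N = 300$):
$F_{\rm obs}/F_{\rm neutral}$ is referred to the $F(n-1, n-1)$
distribution, one-sided lower tail. Rejection means the trait lost
significantly more variance than neutral traits did.

**Group of traits.** When many (putatively independent) selected traits
share a similar architecture, their per-trait $\hat F$ distribution is
compared to that of neutral traits with a Welch two-sample $t$-test
(the sources do not name the $t$-test variant; Welch is the robust
choice). Sampling $n$ individuals (default 20) independently at each time
point, repeated over 100 iterations, gives the simulation-based power
(`estimate_power()`, `power_grid()`).

**Lower bound on loci.** Scanning a ladder of $M$ values, the largest $M$
for which a significant difference from neutrality is found across *all*
parameter combinations is reported by `lower_bound_loci()`; observing no
significant change then argues for an architecture more polygenic than
that bound.

Two estimator facts worth knowing: the ratio of two independent sample
variances at Gaussian data is biased upward by $(n-1)/(n-3)$ (about +12%
at $n = 20$) — the group test is unaffected because both groups share the
bias, but single-trait $\hat F$ values at small $n$ should be read with
this in mind; and the per-trait $F$ at full census uses the same
individuals at both time points only in the sense of the same population —
individuals are distinct across generations, so the two variances are
independent.

## The expression-variance stage

Counts from 2 reconstituted-ancestral + 2 evolved populations (19–22
individuals each) are TMM-normalized (edgeR's implementation; trim
fractions 0.30/0.05, 75th-percentile reference) and converted to
natural-log CPM with a pseudocount of 0.5 (zero handling is not specified
by the sources; 0.5 is the conventional choice and is configurable). The
natural log makes per-gene variances directly comparable across genes and
decouples mean and variance. Per-gene variance change
$F = s^2_{\rm evolved}/s^2_{\rm ancestral}$ is computed only within
same-lot (library-preparation batch) contrasts to avoid confounding —
the generator reproduces this design with lot-shared log-scale offsets.
The direction of $F$ is evolved/ancestral throughout the package (so a
"variance drop to 84%" reads $F = 0.84$).

Uncertainty of per-gene variances is assessed by a leave-one-out
pseudovalue jackknife. The interval is formed on the log scale by default
and back-transformed: variances are positive and right-skewed, and the
log-scale interval restores close-to-nominal coverage at $n \approx 20$
(the raw-scale pseudovalue interval covers at ~90% instead of 95% in the
package's own coverage study).

Read-sampling noise is separated from across-individual biological
variability by the moment partition
${\rm CV}^2_{\rm total} = {\rm CV}^2_{\rm technical} + {\rm CV}^2_{\rm bio}$,
with the technical component modeled as Poisson, $1/\bar{c}$ for mean
normalized count $\bar{c}$, and the biological component the non-negative
remainder, optionally shrunk (default mildly, weight 0.2) toward a lowess
mean–dispersion trend. This is a deliberate, transparent moment estimator,
not a reimplementation of a count-model dispersion fitter; for NB-generated
counts it recovers the generating dispersion (median within 25% at
$n = 50$ in the test suite).

DE labels are ordinarily supplied externally (they stand for genes under
selection on the mean); `de_call_standin()` provides a per-gene Welch
$t$-test with Benjamini–Hochberg control as a stand-in.
`compare_de_vs_nonde()` then contrasts the $F$ distributions of the two
classes, and `replicate_correlation_test()` asks whether the variance
changes of DE genes are more strongly correlated between evolution
replicates than random non-DE gene sets of the same size (permutation
$p$-value with the usual $(1+k)/(B+1)$ finite-sampling correction).

## What the synthetic data emulate — and what they do not

`simulate_expression_counts()` emulates the *structure* of the study
design: NB counts with log-normal gene baselines, per-gene dispersions,
log-normal library sizes, lot-shared batch offsets, a DE subset whose
evolved log-mean shifts by a chosen number of ancestral SDs (ancestral SD
$\approx \sqrt{\phi + 1/\mu}$ on the log scale), and an optional
variance factor on evolved dispersions. It does **not** emulate
gene–gene correlation, GC/length biases, isoform complexity, or the
coupling between mean evolution and the underlying haplotype dynamics —
passing tests on these data show the pipeline's estimators are correct
and calibrated, not that real data meet their assumptions.

Similarly, the founder panel is a synthetic stand-in: linkage
equilibrium among panel loci, a parametric SFS and a uniform map. Real
founder panels carry LD and map heterogeneity that can modulate variance
trajectories quantitatively (not qualitatively).

## Numerical and design choices

* **Problem sizes.** The package's reference analyses use 500-trait
  neutral ensembles and ~1,000-trait selected grids at $N = 300$, 100–103
  generations — ensembles large enough that Monte-Carlo error on mean $F$
  is below 0.01 while a full analysis stays in the minutes range on one
  core. The simulator core is C++ (Rcpp) with R's RNG, so every run is
  reproducible from a single seed.
* **Ties and degeneracies.** Monomorphic panel columns are resampled a
  bounded number of times, then flagged and excluded from architecture
  sampling. Zero ancestral variance flags a gene rather than producing an
  infinite $F$. All-zero fitness signals extinction as an error.
  Identical group distributions report $p = 1$ rather than `NaN`.
* **Optimum-shift scale.** The fitness anchors use the ancestral
  *genetic* standard deviation. The sources describe the scale both as
  genetic and as phenotypic SD in different places; genetic is used
  because it is the quantity the fitness-scaling argument is stated for.
  (With the default heritabilities, the phenotypic SD is about 24% larger,
  i.e. slightly weaker effective selection.)
* **$F$ baseline.** Generation-1 phenotypic variance of the founded $N$
  individuals — not the panel expectation — so $F = 1$ at generation 1 by
  construction and founding noise is shared by numerator and denominator.

## Known limitations

* The paper-scale burn-in (N = 10,000 for 20,000 generations over 5,000
  loci) is supported as configuration but not run in tests; equilibrium
  properties are verified at diffusion-scaled sizes.
* `estimate_power()` flattens module phenotypes; group power analyses are
  defined for single-trait ensembles.
* The expression stage assumes approximate log-normality of CPM within
  populations; very low-count genes violate this and are only partially
  protected by the pseudocount.
* Jackknife intervals for variances are approximate; their coverage was
  verified at Gaussian data, not for heavy-tailed expression noise.

## A worked example

```{r example, eval = FALSE}
panel <- generate_founder_haplotypes(189, 1000, seed = 1)

# one oligogenic trait under a mild optimum shift
arch <- trait_architecture(panel, M = 5, shape = 2.5, h2 = 0.6, seed = 2)
traj <- evolve(panel, arch, fitness_regime("single_trait", a = 1, b = 3.6),
               N = 300, generations = 100, record = c(1, 25, 50, 100),
               seed = 3)
variance_ratio(traj, 100)

# neutral reference ensemble and the single-trait test
neutral <- simulate_trait_ensemble(panel, 200, M = 100,
                                   regime = fitness_regime("neutral"),
                                   N = 300, generations = 100,
                                   record = c(1, 100), seed = 4)
F_neutral <- mean(vapply(neutral, function(tr) tr$F[2], numeric(1)))
single_trait_variance_test(traj$pheno_var[1], traj$pheno_var[4],
                           n = 300, F_neutral = F_neutral)

# expression stage on synthetic counts
cm <- simulate_expression_counts(n_genes = 2000, de_fraction = 0.1,
                                 mean_shift_sd = 1, seed = 5)
res <- analyze_expression(cm)
res$comparison$anc1_vs_evo1
```
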