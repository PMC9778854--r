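---
title: "Models and methods behind driftmeta"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind driftmeta}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(driftmeta)
```

driftmeta studies how extinction–recolonization dynamics shape molecular
evolution in pond metapopulations of cyclical parthenogens such as *Daphnia
magna*. Under the propagule model, empty habitat patches are colonized by one
(occasionally two) founders from a single source, so new subpopulations start
with a strong genetic bottleneck: low diversity within, high differentiation
between. Immigration then slowly restores diversity and erodes
differentiation, so older and better-connected subpopulations should be more
diverse and less differentiated. The package provides the simulation and
estimation machinery to quantify that picture from pool-seq read counts, and
a synthetic-data generator that reproduces its statistical structure for
testing.

This vignette documents the models, the tunable parameters, the numerical
choices, and the limits of what the synthetic data can show.

## The forward simulator

`run_equilibrium()` and `run_substitutions()` simulate a single panmictic
diploid population of constant census size $N$ with discrete, non-overlapping
generations. Reproduction is clonal except every `sex_interval`-th generation
(default 8, roughly one sexual episode per growing season against a backdrop
of clonal turnover). In a clonal generation each offspring copies both
haplotypes of one parent; in a sexual generation it draws two distinct
parents and receives one recombinant gamete from each, with crossover counts
$\mathrm{Poisson}(r\,(L-1))$.

Selection is soft: parents are sampled with probability proportional to
fitness, which is multiplicative across sites with per-site contribution
$1+s$ for homozygotes and $1+hs$ for heterozygotes ($h = 0.5$ by default,
i.e. additive — the common simulator default where nothing else is known).
Exactly how the original non–Wright–Fisher density regulation distributed
reproductive success is not recoverable, so fitness-proportional parent
choice is this package's stated assumption.

New mutations arrive at $\mathrm{Poisson}(2NL\mu)$ per generation at
continuous positions on $[0, L)$ (infinite sites). A mutation is
nonsynonymous with probability `nonsyn_fraction` (default 0.70, the standard
$\approx 2.3:1$ nonsynonymous:synonymous opportunity of coding DNA) and then
receives a selection coefficient from the configured DFE:

* `fixed_zero` — all mutations neutral;
* `gamma_deleterious` — $s = -\Gamma(\text{shape},
  \text{scale} = |\bar s|/\text{shape})$, e.g. mean $-0.03$ / shape $0.2$ or
  mean $-0.05$ / shape $0.5$;
* `gamma_plus_beneficial` — as above, but a small fraction (default 1.5%)
  of nonsynonymous mutations is beneficial with fixed $s$ (default $10^{-4}$).

Synonymous mutations are always neutral. Runs start from a monomorphic
population and burn in for `burnin_multiplier * N` generations (default 10,
the usual mutation–drift equilibration heuristic; exposed because partial
clonality can slow convergence). Diversity is computed per class as
$\pi = \sum_{\text{seg}} 2p(1-p)\,\tfrac{2N}{2N-1} / (L f_{\text{class}})$,
i.e. over segregating sites with the unbiased small-sample correction; the
denominator is the full class site count, so invariant sites dilute as they
should. Substitution runs remove any mutation reaching frequency 1 across
all $2N$ haplotypes and count it in $D_n$ or $D_s$; the fixation scan runs
every 10 generations, which is exact because a fixed allele can never
un-fix without back mutation.

All randomness flows through R's RNG, so a `seed` in `sim_config()` makes
results bit-identical — the reproducibility contract the tests assert.

### Desk-scale parameter choices

Paper-scale runs of this design (a 100 kb coding stretch, $\mu = 10^{-8}$,
1,000 replicates per configuration, 100,000-generation substitution runs on
1 Mb) are long-running. The package's tests and examples rescale to desk
scale while keeping the $N\mu L$ regime comparable: the neutral
$\pi_N$-on-$\pi_S$ slope experiment uses $L = 10^5$, $\mu = 5\times10^{-7}$
and 100 replicates per population size, which keeps expected per-class
segregating-site counts high enough that independent Poisson noise in the
replicate means no longer attenuates the regression slope. The fully sexual
neutral control ($\pi_S \approx 4N\mu$) runs at $N = 100$, $\mu = 10^{-7}$,
$L = 10^4$ with 150 replicates. Substitution-rate checks use 20 replicates
of 20,000 generations at $L = 10^5$. Qualitative selection checks rescale
selection coefficients with the smaller desk-scale $N$ so the population-
scaled strengths $2Ns$ stay in the regime of interest (e.g. beneficial
$s = 0.1$ at $N \le 300$ when probing the adaptive substitution rate).
These sizes are the package's choices for routine verification; any of them
can be scaled back up through `sim_config()`.

## The metapopulation generator

`simulate_metapop()` is the synthetic-data generator: a propagule-model
metapopulation on an explicit map. Its defaults are the study conditions of
the rock-pool system it emulates:

| parameter | default | rationale |
|---|---|---|
| `extinction_rate` | 0.20 / yr | observed pond-turnover rate |
| `colonization_rate` | 0.05 / yr | observed colonization of empty ponds |
| `single_founder_prob` | 0.90 | ~90% of colonizations are single-founder |
| `n_patches` | 300 | ~20% occupancy gives ≈ 60 occupied ponds, a realistic survey |
| `deme_size` | 100 | rock-pool populations of roughly a hundred after clonal expansion |
| `migration_rate` | 5 | immigration scale; see below |
| `migration_decay` | 1/200 m | exponential dispersal-distance decay |
| `source_freq_alpha/beta` | 0.7 | U-shaped metapopulation-wide allele frequencies |
| `years` | 30 | the span of a long-term biannual survey |

Each year, occupied patches go extinct with probability `extinction_rate`;
empty patches are colonized with probability `colonization_rate` by one
diploid founder (else two) sampled at Hardy–Weinberg proportions from the
kernel-weighted frequency mixture of occupied patches; surviving patches
receive $\mathrm{Poisson}(m \cdot S_i)$ immigrants, where
$S_i = \sum_{j \ne i} e^{-d_{ij}/200\,\text{m}}$ is the kernel mass of
occupied neighbors, admixed in proportion arrivals/`deme_size`; and binomial
drift resamples each surviving patch at $2\,$`deme_size` alleles. Newly
founded patches keep their founder frequencies through the founding year —
clonal expansion copies genotypes. Scaling the immigrant *number* by $S_i$
is the design decision that encodes exponentially decaying dispersal: it is
what couples isolation (NN2) to both diversity and differentiation, the two
built-in effects of the generator. A flat arrival count would sever that
coupling and leave isolation with nothing to predict.

`migration_rate = 5` was chosen so that a typical well-connected pond
(kernel mass $S_i \approx 1.5$–4) turns over a few percent of its gene pool
per year — enough that 30 years of immigration visibly homogenizes
neighborhoods — while an isolated pond ($S_i < 0.3$) stays close to its
founder state. Pond coordinates default to overlapping shoreline clusters
plus a sparse background, giving a continuous gradient from dense
neighborhoods to isolated ponds; with spatially disjoint island blocks
instead, most pond pairs sit at maximal differentiation regardless of
isolation and the NN2 signal collapses to within-island contrasts.

`emit_poolseq()` layers the measurement model on top: `pool_size`
individuals (default 50) are sampled binomially, read depth is
negative-binomial (mean 30, size 10), alternate-read counts are binomial in
the pool frequency, and reads are miscalled at `error_rate` (default 0.002).
Depth, surface area and infection status are emitted as pure noise
covariates: only age and isolation carry built-in effects, so regression
calibration can use the noise columns as negative controls.

What the generator does *not* emulate: linkage between loci (loci are
unlinked because all downstream statistics are per-site), a resting-egg
bank, within-pond genealogies, parasite dynamics, and hybrid-vigor-elevated
effective migration. Passing recovery tests on this generator therefore
shows the estimators and the study design are sound under the propagule
model's statistical structure — not that real ponds obey the model.

## Pool-seq estimators

`filter_variants()` applies the variant-filtration rules: sites kept when
QUAL > 30, MQ > 40, QD > 2.0, FS < 60 (strict inequalities; a missing INFO
field fails its rule) and the record is a biallelic SNV; per-sample
genotypes are masked at DP < 10 or minor-allele depth exactly 1 — a
depth-aware error guard, more conservative than a MAF cutoff. Removed
records are attributed to the first failing rule in a fixed order so the
report's counts add up.

`site_pi()` estimates per-site heterozygosity from read counts as
$\frac{D}{D-1}\, 2\hat p(1-\hat p)$ with $\hat p$ the alternate-read
fraction — unbiased for read sampling from the pool. The second binomial
stage (individuals into the pool) is deliberately *not* corrected here; the
pool-size correction enters the FST estimator, where it matters most. This
is a stated simplification, and `region_pi()` documents its bookkeeping:
masked or depth-<2 variant sites leave the denominators ("assayed sites"),
monomorphic sites contribute zero but stay in them, and $\pi_N/\pi_S$ is
flagged undefined rather than silently NaN when $\pi_S = 0$.

`pairwise_fst()` uses the Weir–Cockerham method-of-moments components with
effective allele numbers $n_\text{eff} = hD/(h + D - 1)$ per pool ($h$ =
haploid pool size, $D$ = depth), the double-binomial correction, and
reports a ratio of averages over loci (negative per-site components are
kept). The exact published pool-seq variant behind the original analysis is
not recoverable, so this form is fixed and documented; in the
deep-sequencing limit it agrees with the genotype-based diploid estimator
to $10^{-3}$, which the tests assert. `population_specific_fst()` is the
per-sample mean of pairwise values — a moment-based stand-in for a Bayesian
F-model's deme-specific FST, chosen to avoid reversible-jump machinery
while preserving the quantity's role in covariate regressions.
`mantel_ibd()` tests isolation by distance with a Mantel permutation test on
log10 distances (a deliberate simplification of eigenvector-map redundancy
analysis).

## Divergence statistics

`polarize()` counts, per sample, polymorphisms ($P_n$, $P_s$: both alleles
read-supported after masking) and substitutions ($D_n$, $D_s$: sample
monomorphic *and* different from the outgroup base); a site never enters
both counts. The outgroup allele is taken as the aligned outgroup reference
base; ancestral-state inference is out of scope, and sites with missing
outgroup calls are excluded and tallied. Monomorphism is strict by default;
`mono_threshold = 0.95` relaxes it, off by default. Then
$\alpha = 1 - (D_s P_n)/(D_n P_s)$, $d_N = D_n/S_\text{nonsyn}$,
$d_S = D_s/S_\text{syn}$, $\omega_A = \alpha\, d_N/d_S$ and
$\omega_{NA} = (1-\alpha)\, d_N/d_S$, so $\omega_A + \omega_{NA} = d_N/d_S$
identically. Undefined cases ($D_n = 0$, $P_s = 0$, $d_S = 0$) warn and
return NA instead of silent NaN. Negative $\omega_A$ is expected when
weakly deleterious nonsynonymous variants segregate.

Site denominators come from `cds_site_totals()`: classic Nei–Gojobori
counting with equal weight on the three changes per position and no
transition/transversion weighting (none was specified for this system).
Mutations creating stops count as nonsynonymous by default
(`stop_handling = "exclude"` drops them from numerator and denominator
instead). Codons with ambiguous bases or internal stops are skipped and
tallied. Coordinates are GFF3 1-based inclusive at the interface; phase is
honored by trimming the 5′ prefix, whose bases are reported as
unclassifiable.

## Ecology associations

`nn2_isolation()` is the mean haversine distance (spherical radius
6,371,000 m) to the two nearest other occupied ponds; ties contribute both
values. `age_from_survey()` applies the survey rule: a subpopulation is
newly established when detected after at least three consecutive
non-detections (or at the series start), ages are right-censored at the
survey span, and with per-visit detection probability 0.74 the chance of
missing an extant population three times is $(1-0.74)^3 = 1.76\% < 2\%$.
`covariate_pca()` log10-transforms designated area/length measures,
standardizes, and orients each loading vector so its largest entry is
positive (a sign convention only). `diversity_regression()` is OLS with
marginal (type-II) tests — each term after all others — matching the
principle-of-marginality ANOVA used for diversity–covariate associations;
rank deficiency is an error naming the aliased terms rather than a silent
drop.

## Numerical and degenerate-case conventions

* Fitness products are clamped at zero; if every parent has zero fitness
  the generation falls back to uniform parent choice.
* Kernel mixtures are clamped to $[0,1]$ against floating-point spill.
* If every patch is empty, colonization falls back to the Beta source
  distribution.
* `deme_size = Inf` is a drift-off proxy: binomial resampling is skipped
  and immigrant admixture proportions go to zero.
* FST matrices assert symmetry and a zero diagonal on every construction;
  per-pair shared-site counts are reported so sparse overlaps are visible.
* Mantel tests refuse constant matrices and zero distances (which cannot be
  log-transformed) rather than returning NaN.

## Known limitations

The simulator records no tree sequences and supports no overlapping
generations or spatial structure (the metapopulation generator handles
space, with free recombination between its loci). The pool-seq model draws
each pond's pool independently — no shared library or mapping biases. The
divergence stage assumes a single aligned outgroup base per site; sites
polymorphic in the outgroup are treated as carrying the outgroup reference.
The regression stage offers Bonferroni correction only for screening
underlying ecological variables, and island-of-origin enters as an optional
fixed factor, not a random effect.
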