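---
title: "Models and methods: heterosis, inbreeding, and directional dominance in clonal hybrids"
author: "hetsim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(hetsim)
```

This vignette documents the statistical models behind `hetsim`, the design
of its synthetic-data generator, the numerical choices made where the
design was genuinely open, and the limits of what the package's own tests
establish. No empirical claim is made here beyond what the test suite and
`scripts/acceptance.R` compute.

## The scientific setting

In a clonally propagated hybrid crop, every selected individual is a
hybrid preserved by asexual propagation. When such a population is closed
and selected for the same traits over many generations, between-parent
allele-frequency differences shrink, favorable dominant alleles approach
fixation, and hybrid vigor (heterosis) among within-population crosses
fades — even while the individuals remain highly heterozygous in absolute
terms. Crossing back to genetically divergent (exotic) material restores
both the frequency differences and the heterosis. The package implements
the full measurement chain for this phenomenon on pseudo-diploid SNP-array
data: array calls collapse octoploid genotypes to dosages {0, 1, 2}, and
every statistic operates at that level by design; subgenome-resolved
dosages are out of scope.

## The synthetic-data generator

`simulate_population()` is first-class, tested code and defines the study
conditions for every downstream check.

**Founders.** Per marker, an ancestral allele frequency is drawn uniformly
on (0.15, 0.85); elite- and exotic-group frequencies are then drawn from a
Balding–Nichols distribution around it with divergence parameter
$F_{ST}$ (default 0.2). The generated Weir–Cockerham $F_{ST}$ between the
groups matches the parameter within sampling error (tested at 5,000
markers), and at divergence 0 the pools are indistinguishable. Elite
founders are drawn with a within-group inbreeding coefficient (default
0.1), exotic founders at Hardy–Weinberg. With these defaults the elite
founders sit near $H \approx 0.30$, elite×elite F1s near 0.34,
elite×exotic F1s near 0.42, and S1 selfs near half their parents' $H$ —
the heterozygosity stratification seen in real clonal breeding pools
genotyped on polymorphism-ascertained arrays. Since the simulated founders
are unrelated, F1s are never *less* heterozygous than their parents; the
one-generation $N_e$ estimator is therefore exercised on selfing decay
(where $H_1/H_0 = 1/2$ gives the closed form $-1/(2\ln 0.5) \approx
0.721$) and on published heterozygosity pairs, not on simulated
parent→F1 decay.

**Transmission.** `cross()` transmits one allele per parent per marker;
heterozygous parents transmit either allele with probability 1/2. Markers
are unlinked by default. An optional per-chromosome Haldane model
randomly phases each parent's heterozygous calls once per gamete batch and
then walks a recombination process along the chromosome (positions read
as cM). Because phase is randomized, linkage produces association of
random sign between adjacent markers; dosage-level storage cannot preserve
true phase, and the tests therefore check the *magnitude* of the induced
association.

**Trait architecture.** Each trait has $n_{qtl}$ causal markers with
additive effects $a \sim N(0, \text{scale}^2)$ and dominance deviations
$d = \delta\,|a|$, $\delta \sim N(\delta_\mu, \delta_\sigma)$. Genotype
values are $-a$, $d$, $+a$ for dosages 0, 1, 2. Directional dominance is
$\delta_\mu > 0$ (default 0.8 for the yield-like trait; 0 for the
anthocyanin-like control trait). A `load_fraction` of QTLs (default 0.2
for the yield-like trait) is forced to carry a favorable, nearly dominant
alternate allele ($\delta \sim N(0.9, 0.1)$), so the deleterious allele is
partially recessive — the genetic-load mechanism that makes selfing
depress the trait while heterozygosity masks it.

**Trial.** Plot value = $\mu$ + genetic value + block + year +
genotype×year + residual, all random terms Gaussian with configured
variances (defaults 2, 2, 5, 20 trait-units²; with the default genetic
variance near 40 these give clone-mean $H^2 \approx 0.85$ and
narrow-sense $h^2$ in the 0.5–0.8 range, matching well-replicated clonal
trials). The default layout is 2 years × 3 complete blocks. With
`n_harvests > 1`, "total"-type traits (yield) have the plot-season value
split across harvests, while "mean"-type traits (quality) are observed at
plot level each harvest; `aggregate_harvests()` restores plot-season
records (sum or mean respectively) before modelling, and any per-harvest
noise ends up in the plot residual. The package-default `n_harvests = 1`
generates plot-level records directly; the study-scale drivers under
`analysis/` use 12 weekly harvests.

**What the generator does not emulate.** Linkage disequilibrium between
markers and QTLs (each QTL *is* an assayed marker), ascertainment bias
beyond the uniform ancestral-frequency window, multi-generation selection
and drift, spatial field trends, and genotype-calling intensity artifacts.
Passing tests therefore establish the correctness and calibration of the
estimators under the stated generative model, not their robustness to
array artifacts or LD structure in real data.

## Genotype metrics

QC drops samples below the call-rate threshold first, then markers by MAF
and missingness (defaults 0.90, 0.05, 0.10). Observed heterozygosity is
the fraction of nonmissing heterozygous calls. Two inbreeding estimators
are provided: $F = 1 - H_o$ — the default, because for a clonal hybrid
measured on an array the interesting quantity is the heterozygous genome
fraction itself — and the excess-homozygosity form
$F = (O_{hom} - E_{hom}) / (m - E_{hom})$ with
$E_{hom} = \sum_j (1 - 2 p_j q_j)$ over the individual's nonmissing
markers. They agree in rank (Spearman ρ > 0.95 in tests); the excess form
can be negative for outbred individuals and depends on the panel's allele
frequencies.

Relationship matrices use panel allele frequencies (no external reference)
and per-marker mean imputation for missing calls. $K_A$ is VanRaden
method 1, $K_A = WW^\top / 2\sum p_j q_j$ with $W$ the $2p_j$-centered
dosages over polymorphic markers. $K_D$ uses the classical dominance
covariates $(-2q_j^2,\, 2p_jq_j,\, -2p_j^2)$ scaled by
$\sum (2 p_j q_j)^2$; a panel without a single heterozygous call is
rejected as degenerate. PCA fixes signs by making the largest-magnitude
loading of each component positive, so results are reproducible across
runs and platforms.

## The kernel REML engine

lme4 fits the trial model (grouped random factors are its home ground, and
the EMMs come from emmeans on the genotype-fixed fit; in a balanced design
they equal arithmetic plot means to 1e-8, which is tested). Models with
*arbitrary covariance kernels* — narrow-sense $h^2$, the directional
dominance model, genetic correlations, the marker scan — need a different
engine, and `reml_kernels()` is the package's own: dense average-
information REML with

* a fixed-point (EM-like) fallback direction and step halving, so the
  restricted log-likelihood never decreases across iterations;
* non-negativity by projection onto a small positive bound
  ($10^{-8}\,\mathrm{var}(y)$), with bounded components frozen when their
  gradient points outward;
* convergence when the relative log-likelihood change falls below 1e-8,
  with a 200-iteration cap and a convergence flag on the fit.

On balanced one-way data it reproduces lme4's REML estimates and the
expected-mean-squares (ANOVA) estimators to six decimals, which the test
suite uses as a dual oracle. `ml_kernels()` maximizes the full likelihood
(profiled fixed effects, `optim` on log variance components) for nested
fixed-effect comparisons, since REML likelihoods are not comparable across
different fixed-effect structures; `compare_degree()` reports the ML
likelihood-ratio test for the Ho² term and both REML log-likelihoods.

The engine is dense ($O(n^3)$ per iteration) and intended for the
hundreds-of-individuals regime of clonal trials; the grouped-factor trial
model deliberately stays in lme4.

## Heterosis contrasts

MPH requires both parent EMMs; BPH follows the field's asymmetric rule —
greater-EMM parent for elite×elite, the *elite* parent for elite×exotic
regardless of means (the exotic parent is screened as a donor, and exotic
parents often cannot be phenotyped at all, in which case only BPH exists).
Ties break deterministically by parent ID and are flagged. Contrast
standard errors use the full EMM sampling covariance when the EMM table
carries it, otherwise independent SEs (the mid-parent variance then being
$V_{F1} + (V_{P1} + V_{P2})/4$). Classification uses a per-contrast 5%
two-sided Wald test with no multiple-testing correction — the convention
for these summary tables, exposed as the `alpha` knob.

One calibration subtlety: with additive QTLs segregating, an individual
F1's true deviation from mid-parent is not zero — it is the Mendelian
segregation deviation. The expected MPH over hybrids is zero (tested), but
the per-hybrid significant-contrast rate legitimately exceeds $\alpha/2$.
The type-I calibration of the contrast machinery is therefore verified
under the exact null (no genetic variance), where the two-sided rejection
rate sits at the nominal 5% and the significantly-positive rate at
$\alpha/2$.

## Directional dominance and the marker scan

The homozygosity model $Y = \mu + \beta\,Ho (+ \beta_2 Ho^2) + A + D +
\varepsilon$ centers $Ho = 1 - H_o$ before fitting for numerical
stability, so $\beta$ is the inbreeding-depression slope at the population
mean homozygosity; it supports trait EMMs, BPH, or MPH as responses. A
constant covariate is dropped with a warning. Under the generator's
directional-dominance defaults the fitted slope is negative in ≥ 90% of
replicates, and under $d = 0$ its significance rate stays nominal (both
in the acceptance suite).

The marker scan estimates variance components once on the null model and
reuses them for every marker (the population-parameters-previously-
determined approximation), testing each marker by GLS in the
eigenbasis of $K_A$; exact per-marker REML sits behind `exact = TRUE` and
agrees with the approximation on test data. Null p-values are uniform
(Kolmogorov–Smirnov, tested), the genome-wide threshold defaults to
5e-8, and monomorphic markers are skipped. The with-exotic vs elite-only
comparison treats a locus that is monomorphic or MAF-filtered in the
elite-only panel as contributing no signal there — which is precisely how
fixation hides a locus from within-population mapping.

## Generation-means theory

With genotype values $(-a, d, +a)$ and favorable-allele frequency $p$, the
population mean at inbreeding $F$ is $a(2p-1) + 2pq\,d(1-F)$. The derived
quantities are panmictic MPH $= d(p_1-p_2)^2$, inbred-line MPH
$= d(p_1q_2 + p_2q_1)$ (Lamkey–Edwards terminology), and baseline
heterosis $= 2pq\,dF$, all verified against genotype-frequency enumeration
rather than asserted. Everything is additive across unlinked loci, and the
multi-locus bridge to the simulator — observed mean MPH of simulated F1s
equals $\sum_j d_j (p_{1j} - p_{2j})^2$ within sampling error — is a
tested property. The decay curves make the fixation argument quantitative:
as $p \to 1$ in both pools, every heterosis measure goes to zero no matter
how large $d$ is.

## Numerical and design choices

* "MAF < 0.05" is the interpreted filter threshold (a 5% minor-allele
  frequency), configurable.
* Eq-style report arithmetic uses percent change $100(\bar y_{S1} -
  \bar y_{S0})/\bar y_{S0}$, so depression is negative — matching the sign
  convention of the published tables it mirrors.
* Duo/trio ratios exclude a marker if *any* member of the duo/trio is
  missing there, keeping $m$ and the ratios comparable across candidates.
  The forensic pass/fail threshold defaults to 0.01, which comfortably
  separates true relations (0 without error; ~0.007 mean TTR at 0.5% call
  error) from unrelated pairs (≈ 0.09–0.13 at realistic frequencies).
* The genetic-correlation model is bivariate REML with an unstructured
  2×2 additive covariance on mean-centered, unit-scaled EMMs; the p-value
  is the upper-tail normal probability of the covariance Z-ratio, and a
  method-of-moments fallback (correlation of single-trait BLUPs) is
  flagged if the optimizer fails.
* Problem sizes in the test and acceptance suites (50 REML recovery
  replicates at 300 genotypes × 2 years × 3 blocks; 25–50 replicates for
  slope-sign recovery; 1,000–2,000 markers for forensics and scan
  calibration) were chosen as the smallest designs at which the checked
  properties are statistically decisive.

## Known limitations

Dense REML limits kernel models to a few thousand individuals. The
simulator's unlinked, LD-free markers mean marker-scan power results do
not translate directly to tag-SNP settings. Linkage simulation uses
random phasing (see above). Octoploid dosage is collapsed to array calls
throughout — intentionally, since every statistic in scope is defined on
those calls. Real-data idiosyncrasies (call-intensity clusters, null
alleles, pedigree errors beyond random swaps) are representable only
through the generic error-injection layer.
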