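---
title: "The admixed full-sibling design: models, simulator and sensitivity analyses"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The admixed full-sibling design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem and the design

Mean phenotype differences between two ancestral populations mix genetic and
environmental causes: genetic ancestry is correlated with socio-economic and
cultural environment, so regressing a phenotype on an individual's ancestry
proportion (the fraction of the genome derived from population 1, written
`Q`) estimates the difference in mean *phenotype* values (`deltaY`), not the
difference in mean *genotypic* values (`deltaG`).

Full siblings break this confounding. Both siblings inherit, in expectation,
the mean ancestry of their parents and share their rearing environment, but
random recombination makes their realised ancestry proportions differ by a
small amount (`dQ`, mostly under 5 percentage points). Under the single
assumption that this within-pair difference is independent of within-pair
environmental differences, the regression of the within-pair phenotype
difference `dy` on `dQ` estimates `deltaG` free of family-level environmental
confounding.

Three regression models implement the design:

* **Model 1a** (individual level): `Y_i = a + bY*Q_i + bA*Age_i + bS*Sex_i +
  e_i`. The slope `bY` estimates `deltaY`.
* **Model 1b** (pair differences): `dy_j = a + bG*dQ_j + b1*dAge_j +
  b2*Age_j1 + b3*dSex_j + b4*Sex_j1 + e_j`. The slope `bG` estimates
  `deltaG`.
* **Model 2** (mixed): `y_ij = a + bW*(Q_ij - Qbar_j) + bB*Qbar_j + b*Age +
  b*Sex + gamma_j + e_ij` with a family random intercept; `bW` estimates
  `deltaG` and `bB` estimates `deltaY`, while correctly handling families
  that contribute more than one sibling pair.

Effect sizes are reported per percentage point of ancestry (the estimate on
the `[0, 1]` scale divided by 100), because observed sibling differences
rarely exceed a few percentage points and effects should not be extrapolated
across the whole ancestry range. p-values are computed on rank-based
inverse-normal transformed phenotypes while effect sizes are reported on the
raw scale; `estimateEffects()` reproduces this dual convention and applies
Benjamini-Hochberg FDR correction across phenotypes within each model.

## The population simulator

Real cohorts of this design (recently admixed populations with large
sibships) are controlled-access, so the package ships a generative model of
the *statistical structure* the analysis assumes.

* **Genetic map.** 22 autosomes with sex-averaged lengths summing to 35.44
  Morgans (`geneticMap()`). The map determines the variance of sibling
  ancestry differences; no external map files are needed.
* **Ancestral allele frequencies.** Balding-Nichols: each population's
  frequency at a locus is Beta-distributed around a shared base frequency
  with divergence parameter FST (`simulateAncestralFreqs()`). The default
  FST of 0.12 gives two-way ancestry estimation accurate to a percentage
  point or two at a few thousand loci, mirroring populations whose ancestry
  components are distinct enough to estimate reliably. The exact divergence
  between the motivating populations is not published; 0.12 is a package
  default, configurable.
* **Founders.** Haplotype tracts follow a stationary approximation of
  admixture `g` generations ago (default 5): tract boundaries are Poisson
  with rate `g` per Morgan and segment ancestries are i.i.d. Bernoulli with
  the founder's target proportion. Default founder composition is 55%
  unadmixed population 1, 5% unadmixed population 2 and 40% admixed with
  Beta(5.68, 2.32) targets (mean 0.71), which reproduces a population mean
  near 71% ancestry 1 and guarantees that same-ancestry, F1-producing and
  admixed families all occur, exercising every downstream filter.
* **Meiosis.** Haldane model: per chromosome, crossover count Poisson with
  mean the genetic length in Morgans, uniform positions, no interference,
  random starting haplotype. Crossover interference is irrelevant at the
  genome-fraction resolution this design uses.
* **Genotypes.** Founder haplotypes draw each allele from the carrying
  ancestry's frequency; offspring copy parental alleles along the
  transmitted-gamete origin tracts recorded at meiosis. Allele transmission
  (not merely ancestry sharing) is what gives sibling pairs their
  (0.25, 0.5, 0.25) IBD structure, which the relatedness estimator relies
  on.
* **Phenotypes.** `y = alpha + Q*deltaG + env + gamma_fam + betaAge*Age +
  betaSex*Sex + eps`, with `env` an optional ancestry-by-environment term
  acting on the family mean ancestry or on the individual ancestry
  (`phenotypeConfig()`). Ages are uniform on 18-80 and sexes Bernoulli(1/2);
  covariate effects default to zero - they exist to exercise the model
  formulas, not to carry signal.

What the simulator does **not** emulate: linkage disequilibrium beyond
ancestry structure, genotyping and imputation error, phenotype
non-normality, assortative mating, and X-chromosome inheritance. Tests that
pass on this generator therefore validate the estimators under the design's
own assumptions; they do not certify robustness to violations the generator
cannot produce.

## Ancestry estimation

`estimateAdmixtureSupervised()` maximises, per individual, the binomial
likelihood with locus success probability `q*f1 + (1-q)*f2` over `q` in
`[0, 1]` (one-dimensional search plus exact boundary evaluation).
`estimateAdmixtureUnsupervised()` estimates proportions and both frequency
vectors jointly by block EM for K = 2, accelerated by guarded squared
extrapolation (SQUAREM): extrapolated candidates are accepted only when they
improve the log-likelihood, so the reported trace is non-decreasing - the
property the tests assert. Numerical choices: frequencies clamped to
`[1e-6, 1 - 1e-6]` to avoid `log(0)`; `q` initialised uniform on
`(0.2, 0.8)` and frequencies from perturbed sample frequencies under the
caller's seed; convergence at a log-likelihood gain below `1e-6` per EM
step, capped at 2000 steps. The two components are exchangeable, so labels
are aligned with a user-supplied anchor set of known population-1
individuals (in the motivating studies this role is played by a reference
panel); without anchors the majority component is labelled population 1,
with a warning.

A semi-supervised mode (`fixedQ`) holds reference-panel individuals at
their known proportions during EM, as supervised admixture software does.
At desk scale this matters: in a sample that is mostly population 1, the
minority component's frequencies are weakly identified, and the resulting
frequency error biases the boundary estimates - truly unadmixed
individuals land at 0.93-0.97 rather than near 1, which degrades the
95%-ancestry filter. Fixing a panel of each population (50 individuals in
the end-to-end tests, mirroring the reference panels such studies include)
anchors both frequency vectors with hard allele counts, roughly halves the
ancestry RMSE and speeds convergence.

## Relatedness and sibling identification

`estimateK()` estimates the genome fractions `(k0, k1, k2)` shared 0/1/2
alleles identical by descent by maximum likelihood, substituting
individual-specific allele frequencies `pi_il = q_i*f1_l + (1-q_i)*f2_l`
into the standard IBD-conditional genotype-pair probabilities; shared
alleles use the pair-average frequency. This is a deliberate simplification
of haplotype-level admixture-aware relatedness models: it keeps the
correction that matters (admixture shifts expected genotype frequencies per
individual) while remaining a per-locus mixture whose weights are fitted by
EM on the simplex. A minimum of 200 informative loci is enforced; below
that the estimate is unstable.

Full siblings are the pairs with `0.25 < k1 < 0.75` and `0.15 < k2 < 0.5`,
plus a boundary rescue: pairs with `0.4 < k1 < 0.6` and `k2 > 0.125` whose
two members are each already siblings of someone else in the primary set.
Sibships are connected components of the resulting graph.

Two filters then remove pairs that carry no ancestry-difference signal:
pairs where both members have more than 95% of the same ancestry (parents
unadmixed and identical, so `dQ_true = 0`), and candidate F1 pairs - both
estimated proportions inside a central band, default `[0.40, 0.60]` - whose
parents are unadmixed with different ancestries (again `dQ_true = 0`
exactly). The band bounds are configurable because the motivating analysis
displays the candidate region graphically without printing bounds. Parental
proportions come from the simulation truth or from a user-supplied table;
reconstructing parental ancestry from offspring haplotypes is out of scope.
Central-band pairs with unknown parents are dropped by default
(conservative) or kept on request. Because every F1 sibling has exactly 50%
of each ancestry, the mean absolute estimated ancestry difference across F1
pairs (`estimateDqErrorFromF1()`) is a pure estimate of the `dQ` error; for
per-individual Gaussian error with standard deviation `sigma` its
expectation is `2*sigma/sqrt(pi)`.

## Sensitivity analyses

All three analyses condition on a fixed sibling-pair population (ancestry
proportions, ages, sexes, families) and redraw phenotypes per replicate,
estimating `deltaY` by model 1a and `deltaG` by model 1b.

* **Ancestry-by-environment** (`simEnvInteraction()`): family mode draws
  `y ~ N(Q*deltaG + E_anc*Qbar, sigma^2)`; the family term cancels in
  within-pair differences, so `deltaG` stays unbiased for any `E_anc` while
  `deltaY` is pulled. Individual mode draws
  `y ~ N(Q*deltaG + E_anc*Q, sigma^2)` and shifts the `deltaG` estimator by
  exactly `E_anc`. Defaults follow the motivating setup: `deltaG = 1`,
  `sigma = 1`, 10,000 replicates per grid value, grid
  `{-2, -1, -0.5, 0, 0.5, 1, 2}`.
* **Participation bias** (`simParticipationBias()`): individuals whose
  phenotype exceeds a quantile threshold fail to participate with
  probability 0.2; non-participants' phenotypes are redrawn until below the
  threshold, keeping the sample size fixed. This truncation attenuates
  `|deltaY|` but barely moves `deltaG`, which uses only within-pair
  contrasts. In mother mode a phenotype is simulated for each family's
  mother from her own ancestry proportion, and flagged families' pairs are
  excluded from that replicate (no replacement) - our reading of
  participation acting through the mother, which probes ancestry-dependent
  selection of whole sibships; both estimators remain nearly unbiased.
  Threshold quantiles default to `{0.5, 0.7, 0.9}`.
* **Ancestry-estimation error** (`simQError()`): phenotypes are generated
  from true `Q`, then independent `N(0, sigma_Qerror^2)` errors are added
  to each individual's proportion before fitting model 1b. The slope is
  attenuated by the classical errors-in-variables factor
  `Var(dQ)/(Var(dQ) + 2*sigma_Qerror^2)`; the larger the error, the larger
  the downward bias. The grid is read as standard deviations in
  `[0, 0.05]` (100 random values by default, 10,000 replicates each, i.e.
  one million simulations in total), and the induced mean absolute `dQ`
  error is reported per grid point so results can be anchored to the
  F1-based error estimate of a real dataset. Errors are per-individual by
  default and switchable to per-pair.

Because these simulations condition on a synthetic population rather than a
specific cohort's estimated proportions, bias *magnitudes* depend on the
`dQ` distribution and are reproduced qualitatively, not numerically.

## Problem sizes and numerical conventions

The test suite and the acceptance script use sizes chosen to keep
Monte-Carlo error well inside the asserted tolerances: 2,000 sibling pairs
for the IBD expectation (standard error about 0.002 per coefficient), a
population of roughly 1,700 admixed pairs with 10,000 phenotype replicates
for the family-interaction check (Monte-Carlo standard error about 0.02 on
the mean `deltaG` estimate), 500-1,000 replicates per grid value for the
attenuation and participation checks, and a 60-family, ~5,000-post-QC-locus
end-to-end run for unsupervised estimation, sibling classification,
filtering and parameter recovery. Sibling pairs are differenced in
lexicographic id order (the model-1b slope is invariant to the choice);
the quantile transform uses the Blom offset 3/8 with average ranks for
ties; FDR correction is Benjamini-Hochberg step-up; model 2 is fitted by
REML with Satterthwaite degrees of freedom, falling back to the
`sigma_gamma = 0` fixed-effects fit when the random-effect variance is
singular.

## Known limitations

* The unsupervised EM is a desk-scale estimator: adequate to a few hundred
  individuals and a few thousand loci, not a replacement for production
  admixture software on biobank data.
* With a few thousand loci the per-individual ancestry error (1-3
  percentage points here) is of the same order as true sibling differences,
  so `deltaG` estimates from estimated proportions are noticeably
  attenuated - exactly the phenomenon `simQError()` quantifies. Real
  analyses at hundreds of thousands of loci sit far down that error curve.
* The relatedness model treats loci as independent given ancestry
  proportions; it does not model IBD segment lengths or phase.
* Model 1b standard errors treat pairs as independent; families
  contributing several pairs induce mild undercoverage, which is why
  model 2 is fitted alongside.
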