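---
title: "Modelling dairy heat stress with reaction-norm test-day models"
author: "thermoRRM"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling dairy heat stress with reaction-norm test-day models}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(thermoRRM)
```

## The problem and the model

Lactating dairy cows dissipate large amounts of metabolic heat, and above a
comfort threshold their milk production declines roughly linearly with
ambient heat load. The standard way to quantify that load is the
temperature-humidity index

$$THI = (1.8\,t + 32) - (0.55 - 0.55\,rh)(1.8\,t - 26),$$

with temperature $t$ in °C and relative humidity $rh$ as a proportion. Mean
daily THI is averaged over hours, and the value attached to a milk-recording
("test-day") record is the mean over the three days preceding the test,
reflecting the lag between heat exposure and milk synthesis. The regression
covariate is the broken stick $f(THI) = \max(0, THI - THI_{thr})$ with
$THI_{thr} = 68$ by default: zero in the comfort zone, one unit per THI
degree above it.

Each cow's production is modelled as a reaction norm on $f$: an intercept
(merit in the comfort zone, the *general* effect) and a slope (change per
unit of heat load, the *thermotolerance* effect), for both additive-genetic
and permanent-environment terms, with lactations 1–3 treated as separate
traits of one multi-trait repeatability model:

$$y_{klmn} = HTD_{kl} + DIM_m + a_{nl} + pe_{nl}
  + \big(v_{nl} + q_{nl}\big) f(THI) + e_{klmn}.$$

Here $HTD$ is the herd × test-date × parity contemporary group, $DIM$ a
20-day days-in-milk class (classes anchored at DIM 5, the last class
absorbing the remainder to 305), $a/v$ the additive intercept/slope pair of
animal $n$ in parity $l$, and $pe/q$ the corresponding permanent-environment
pair of the cow. Stacking the three parities, the additive pairs follow
$\mathrm{Var}(a) = A \otimes \Phi$ with $A$ the pedigree numerator
relationship matrix and $\Phi$ the $6 \times 6$ coefficient covariance
matrix; permanent effects follow $I \otimes \Psi$; residual variances are
heterogeneous by parity ($R = \mathrm{diag}(\sigma^2_{e,1..3})$) but
homogeneous across THI within parity.

Key derived quantities, evaluated per posterior draw and then summarised:

* heritability at heat load $f$:
  $h^2(f) = \dfrac{\sigma^2_a + f^2\sigma^2_v + 2f\sigma_{av}}
  {\sigma^2_a + f^2\sigma^2_v + 2f\sigma_{av} + \sigma^2_{pe} +
   f^2\sigma^2_q + 2f\sigma_{pq} + \sigma^2_e}$;
* general × thermotolerance genetic correlation
  $f\sigma_{av}/\sqrt{\sigma^2_a f^2 \sigma^2_v}$, which is independent of
  $f > 0$ — the reported value at $f = 10$ equals the plain correlation of
  intercept and slope effects;
* across-parity correlations of the intercepts (`cor_gen`) and slopes
  (`cor_ht`), read off the corresponding sub-blocks of $\Phi$.

Summarising per-draw functionals rather than plugging posterior means into
the formulas is deliberate: a ratio of means is not the mean of ratios, and
the highest-posterior-density intervals reported next to each functional
only make sense on the functional's own posterior.

## Estimation

Variance components are estimated by Gibbs sampling (`gibbsSampler()`):
location effects are updated blockwise (scalar nodes for fixed levels,
$2P$-dimensional blocks per animal and per cow, which mixes far better than
single-site updating under the strong intercept–slope coupling); $\Phi$ is
drawn from its inverse-Wishart full conditional with scale equal to the
prior scale plus $U' A^{-1} U$ over the animal coefficient matrix $U$;
$\Psi$ analogously over cows; each parity's residual variance from a scaled
inverse chi-square. Priors are inverse-Wishart with degrees of freedom
$2P + 2$ and scale set to the initial values — so the prior mean equals the
starting values, which play the role of literature estimates — and a 4-df
scaled inverse chi-square for residuals; fixed effects are flat. All
randomness flows through R's RNG, so a seeded chain is bit-reproducible.

The default desk-scale protocol is 20,000 iterations with 5,000 burn-in and
thinning 10 (1,500 retained draws); `chainPresetFull()` supplies the
full-scale 500,000 / 100,000 / 100 protocol (4,000 retained draws) for
production runs. Convergence is screened with an advisory Geweke z-score per
component in `posteriorSummary()`; it is a screen, not a proof, and long
runs should also be inspected via `plotTrace()`.

Pedigree machinery: $A^{-1}$ is assembled directly and sparsely by
Henderson's rules with Meuwissen–Luo inbreeding coefficients — ignoring
inbreeding visibly biases $A^{-1}$ on pedigrees a few generations deep, and
the simulated pedigrees here do accumulate inbreeding. Effect solutions for
a *given* set of variance components come from a direct sparse Cholesky
solve of the mixed-model equations (`solveMME()`); with system sizes up to a
few times $10^4$ a direct solve is both faster and more transparent than an
iterative solver, and its relative residual (reported) is at machine
precision. One DIM class per parity is the identifiability baseline; if the
data leave further fixed-effect levels confounded (possible in small or
oddly structured herds), those levels are detected by pivoted QR and
constrained to zero rather than letting the solve fail.

## Single-step genomic scan

Genomic mapping uses single-step GBLUP: the pedigree precision $A^{-1}$ in
the mixed-model equations is replaced by

$$H^{-1} = A^{-1} +
\begin{bmatrix} 0 & 0 \\ 0 & G^{-1} - A_{22}^{-1} \end{bmatrix},$$

where $G$ is the genomic relationship matrix of the genotyped animals and
$A_{22}$ their pedigree block. $G$ is the centred cross-product
$ZZ'/2\sum_j p_j(1-p_j)$ with observed allele frequencies, blended as
$0.95\,G + 0.05\,A_{22}$ — the conventional safeguard that keeps $G$
invertible; no further scaling of $G$ to $A_{22}$ is applied (both the blend
and the skipped tuning are exposed as arguments for sensitivity analysis).
Genomic information enters only this mapping solve; variance components are
estimated from pedigree and phenotypes alone.

SNP effects are backsolved from the GEBV component of interest (general
$\hat a$ or thermotolerance $\hat v$, per parity) as
$\hat s = DZ'(ZDZ')^{-}\hat a_g$ with equal SNP weights and a spectral
pseudo-inverse (relative eigenvalue cutoff $10^{-10}$; with more SNPs than
animals $ZDZ'$ is singular by construction, and the pseudo-inverse returns
the minimum-norm preimage). Windows of 2.0 Mb, anchored at every SNP
(half-open $[anchor, anchor + 2\,\mathrm{Mb})$, same chromosome; a distinct
tiling is available via `tiling = TRUE`), are scored by
$100 \cdot \mathrm{var}(\sum_{j} Z_j \hat s_j)/\sigma^2_u$, where the
variance runs over genotyped individuals. The denominator $\sigma^2_u$ is
the variance of the total genomic value $Z\hat s$ of the same component —
the alternative (a total additive variance from the variance components) is
not used because it mixes pedigree-only variation into a genomic
decomposition; the choice matters only as a common scale factor within one
scan.

## Gene-set analysis

SNPs are assigned to every gene whose interval, extended 15 kb on both
sides (strand-agnostic, coordinates 1-based inclusive; BED input converted
on ingest), covers their position. Per parity, the *relevant* SNPs are the
top 5% of the thermotolerance effect distribution in absolute value, ties
included at the boundary so equal-magnitude effects are never dropped; a
gene is a candidate when it is hit in at least two parities. Enrichment of
each gene set is the upper-tail hypergeometric probability of the observed
overlap (Fisher's exact test); the gene universe defaults to the genes with
at least one assigned SNP — the most defensible choice when the annotation
is consumed as a file — and is configurable. An FDR column is emitted for
reference, but the headline significance call is the uncorrected
$p \le 0.05$, matching the usual reporting of such scans.

## What the synthetic generator emulates — and what it does not

`simulateStudy()` generates, from one seed: a discrete-generation
random-mating pedigree whose final all-female generation supplies the
phenotyped cows; biallelic genotypes gene-dropped through it (founder
frequencies uniform on [0.05, 0.5]); a seasonal daily THI series
(sinusoid + Gaussian noise, default mean 72, amplitude 7, noise SD 2.5 —
about 250 days above the threshold per year, a subtropical pattern); and
test-day records generated under the model above, with herd-synchronised
monthly tests, calving in the first 60 days of each parity-year, DIM in
[5, 305] and ≥ 6 tests per lactation by construction.

True breeding-value pairs are produced by the pedigree recursion
(child = parent average + Mendelian deviation scaled by
$0.5 - 0.25(F_s + F_d)$), which realises $A \otimes \Phi$ exactly without a
dense Cholesky and scales to thousands of animals. Optional QTL are added on
top of the polygenic term from centred genotype codes; $\Phi$ is *not*
re-normalised, and the realised variance contribution is reported in the
truth object. A QTL can be specified by per-allele effect or by
`var_share` — the fraction of the component's polygenic variance it should
explain at the realised marker variance — which removes allele-frequency
luck from planted-signal experiments.

Default variance components are the published Florida Holstein estimates
(`referenceVarianceComponents()`); the across-parity blocks of $\Phi$ use
the published `cor_gen`/`cor_ht` correlations, and the unpublished
intercept-of-parity-$i$ × slope-of-parity-$j$ correlations are filled with
the symmetrised path rule
$\tfrac12(\mathrm{cor\_gen}_{ij} r_j + \mathrm{cor\_ht}_{ij} r_i)$, the
mildest completion consistent with the published margins; the resulting milk
$\Phi$ is verified positive definite at construction. Permanent-environment
components are unpublished; they default to half the corresponding additive
components ($\Psi = 0.5\,\Phi$), a magnitude typical for repeatability
test-day models.

The generator deliberately omits: linkage disequilibrium beyond family
structure (SNPs are dropped independently), selection and assortative
mating, herd-level heteroscedasticity, missing genotypes, and weather-station
heterogeneity. Passing tests therefore demonstrate that the machinery
recovers what the model assumes — not that real Holstein data meet those
assumptions; in particular, LD-driven window signals around a causal variant
will be wider in real data than in these simulations.

## Validation design and problem sizes

The test suite validates each stage against an independent oracle (tabular
relationship recursion, dense mixed-model assembly, SVD pseudo-inverse,
brute-force window variance, hypergeometric enumeration, exhaustive HPD
scan) and then closes the loop with three simulation studies, sized to run
comfortably on a single CPU:

* **Parameter recovery** — ten replicates of 1,500 phenotyped cows
  (≈ 15,000 records, ≈ 2,600 animals) simulated under the parity-1 milk
  components, each fitted with a 20,000-draw chain. Checks: HPD coverage of
  each component in ≥ 8/10 replicates; the mean posterior mean of
  $\sigma^2_a$ within 15% of truth; the recovered general × thermotolerance
  correlation within ±0.15 of the simulated −0.41 in ≥ 8/10.
* **Planted-QTL mapping** — ten replicates of 500 genotyped cows with a
  slope QTL sized to 80% of the slope polygenic variance; the window
  containing the QTL must rank first among thermotolerance windows in
  ≥ 9/10. The 80% share defines "large effect" here; at 50% the design is
  underpowered at this cow count, which says nothing about the machinery.
* **Null enrichment calibration** — 1,000 draws of 200 null candidates from
  a 1,000-gene universe. Because hypergeometric p-values are discrete, the
  attainable size of a 0.05-level test is below 0.05 for small sets; the
  check compares the empirical rejection rate against the *exact* attainable
  level per set size (and against nominal for the near-continuous largest
  set), and asserts the test is never anti-conservative.

## Numerical choices and degenerate inputs

* Humidity is a proportion; percent-scale input is rejected, not rescaled
  (`rhPercent = TRUE` converts explicitly at ingest). Silent acceptance of
  percent humidity would corrupt every downstream covariate.
* The heat-load threshold, DIM class width, record-edit rules, G-blend and
  window size are arguments with the defaults above, not constants.
* Covariance draws that fail a Cholesky (numerically non-PD scale matrices
  in extreme chain states) are retried with an escalating diagonal ridge and
  counted in the chain metadata (`jitter`); a clean run reports zero.
* `f = 0` makes the general × thermotolerance correlation undefined (its
  defining expression divides by zero) and is an error; a negative genetic variance
  at some $f$ (possible with strongly negative $\sigma_{av}$ in chain tails)
  yields a warning, not an error, so per-draw summaries stay robust.
* HPD intervals are the shortest empirical window at the requested mass,
  ties resolved toward the smaller lower bound.
* A single record per fixed-effect cell is absorbed by the cell estimate and
  contributes nothing to the random effects — the expected degenerate
  behaviour, exercised in the tests.

## Known limitations

Residuals are homogeneous across THI within parity; no heterogeneous-THI
residual bands, no lactation-curve random regressions beyond the DIM
classes, no APY or other large-$n$ approximations of $H^{-1}$, no unknown
parent groups or metafounders, and no iterative SNP reweighting in the scan.
Parities beyond 3 are dropped at validation. These mirror the intended scope
of the analysis rather than technical limits of the implementation.

## A worked pipeline run

```{r pipeline, eval = FALSE}
cfg <- runConfig(
  sim = simulationConfig(seed = 5, nCowsPhenotyped = 80, nFounders = 40,
                         nSnps = 150, parities = 1:2,
                         qtl = data.frame(chr = "2", pos = 1e7,
                                          component = "v", effect = NA,
                                          var_share = 0.8)),
  chain = list(total = 1500, burnin = 500, thin = 5))
runPipeline(cfg, "run5")
read.delim("run5/top_windows.tsv")
```

The `fit` stage writes the retained chain and posterior summaries; `params`
the per-draw genetic-parameter summaries; `scan` the SNP-effect and window
tracks per component; `enrich` the candidate genes and enrichment table.
Every stage records its inputs, checksums, seed and timing in
`manifest.json`, and a completed stage is not re-run without `force`.
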