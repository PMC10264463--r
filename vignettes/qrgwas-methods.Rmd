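---
title: "Quantile-regression GWAS on simulated composite populations: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantile-regression GWAS on simulated composite populations: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qrgwas)
```

qrgwas is a simulation laboratory for a question plant breeders care about:
when the number of genotyped and phenotyped individuals is small, can a
genome-wide association scan based on quantile regression (QR) still find
quantitative trait loci (QTLs) that an ordinary least-squares scan misses?
The package provides every stage needed to study that question end to end:
a forward population simulator with known QTLs, linkage-disequilibrium (LD)
decay analysis that calibrates QTL detection windows, population-structure
correction, per-marker QR and OLS scans with false-discovery-rate control,
and a scenario engine that estimates detection power and false-positive
rates across population sizes, heritabilities and genetic architectures.

## The simulated breeding design

The genome is 10 chromosomes of 200 cM carrying 2000 biallelic SNPs (200
per chromosome, one marker per cM) and 100 QTLs placed uniformly at random
in the marker-covered region. All loci are simulated jointly and phase is
tracked internally; only dosages in {0, 1, 2} are exposed to the analysis
stages.

A note on the marker geometry: a 2000-SNP genome on 10 x 200 cM
chromosomes fixes the average spacing at one marker per cM, which is the
default here (`spacing_cM = 1`). Spacing, marker counts and chromosome
lengths are all configuration fields of `build_genome_map()` and
`sim_config()`, so denser designs can be simulated directly.

The population is an *advanced-generation composite*: two random-mating
parental populations, each in linkage equilibrium, are crossed and the
cross is advanced by random mating. The composite is the classical way to
create LD for mapping, because the gamete-pool LD after the cross is

$$\Delta_{ab} = \frac{1 - 2\theta_{ab}}{4}\,(p_a^1 - p_a^2)(p_b^1 - p_b^2),$$

proportional to the product of the parental allele-frequency differences
and maximal ($|\Delta| = 0.25$) for completely linked loci fixed for
alternative alleles (`expected_composite_ld()`). The simulator implements
this mechanically rather than by formula: generation 0 consists of 100
full-sib families (5000 individuals) bred from F1 parents that carry one
haplotype from each parental population, so the gamete pool forming
generation 0 carries exactly $\Delta_{ab}$; a property-based test verifies
this against the closed form. Five generations of random mating follow
(no mutation, selection or migration), and the study sample is 20 full-sib
families of 50 (N = 1000) bred from random parent pairs of the final
generation. Meiosis follows the Haldane model - crossovers as a Poisson
process along the genetic map, one expected crossover per Morgan, no
interference - since only map distances in cM are specified by the design;
recombination fractions are therefore $\theta(d) = (1 - e^{-2d/100})/2$.

Parental allele frequencies are the one genuinely free quantity of the
design, and everything downstream (LD level, marker informativeness,
structure) is a function of them. The default law (`freq_law("divergent",
delta = 0.05)`) draws, per locus, one parent's frequency in
$U(1-\delta, 1)$ and the other's in $U(0, \delta)$ with random
orientation: near-fixed, strongly diverged parents, i.e. the maximal-LD
regime the composite design is built to exploit. We calibrated `delta`
once against the study conditions the design is meant to emulate - markers
must tag nearby QTLs strongly enough that a well-powered scan at N = 1000
detects a meaningful fraction of 100 small QTLs, and the LD decay curve
must cross the critical $r^2 = 0.20$ level inside the observed distance
range at every population size from 1000 down to 200 - and froze it. A
milder `uniform` law and a degenerate `fixed` law are available; with
weakly diverged parents (e.g. frequencies uniform on (0.05, 0.95)) the
squared dosage correlation never reaches 0.20 at any distance and no
detection window exists, which is worth knowing before designing a
composite mapping study.

Population-size scenarios are produced by `downsample()`: repeated random
reductions of 100 individuals that remove exactly the same number from
every family, preserving the family proportions at each step
(1000, 900, ..., 200).

## Traits

Two architectures are simulated on the same 100 QTL positions.
`infinitesimal_100` assigns each QTL an i.i.d. normal additive effect.
`major3_plus97` designates 3 random polymorphic QTLs as major genes and
rescales their effects so the major component accounts for exactly half of
the realized genetic variance in the study population - realized meaning
the variance of $g_i = \sum_q x_{iq}\beta_q$ including the LD covariances
among QTLs, not an idealized $\sum 2pq\beta^2$ sum; the rescaling solves
the quadratic in the scale factor so the 50/50 split holds with the
major-minor covariance included. Phenotypes add independent
$N(0, \sigma^2_e)$ noise with $\sigma^2_e = \mathrm{var}(g)(1-h^2)/h^2$, so
the broad-sense heritability (here equal to narrow sense, all action being
additive) matches its target of 0.30 or 0.50 exactly in the realized
variances. Effects are redrawn in every replicate.

## LD decay and detection windows

Whether a scan "detected a QTL" is defined through LD: `pairwise_r2()`
computes $r^2$, the squared Pearson correlation of dosage columns, for all
same-chromosome marker pairs (~199,000 pairs in the default genome;
monomorphic markers are skipped with a warning). A locally weighted
polynomial regression of $r^2$ on distance is fitted (span 0.75, degree 2,
tricube weights - the classical LD-decay smoother), and the detection
window half-width $w$ is the smallest distance where the fitted curve
crosses the critical level $r^2 = 0.20$, found by grid bracketing plus
bisection (`window_distance()`). A marker is *QTL-associated* if it lies
within $w$ of a target QTL on the same chromosome; the targets are the 3
major genes under `major3_plus97` and all 100 QTLs under
`infinitesimal_100`.

The local-polynomial fit is computed from per-distance sufficient
statistics rather than through `stats::loess`, for one reason: on a 1-cM
grid the crossing can fall below the smallest observed pair distance,
where `loess` cannot be evaluated without the quadratic-cost "direct"
surface. The evaluator uses the same span-fraction nearest-neighbour
bandwidth and tricube weights as `loess` - the two agree to numerical
tolerance on interior points, which a test asserts against
`stats::loess(surface = "direct")` - but remains evaluable at any
non-negative distance, where the boundary-local polynomial extends
smoothly. The window is recomputed per replicate and per population size;
windows widen as N shrinks because the sampling floor of $r^2$ (of order
1/N with an effective N set by the family structure) lifts the whole
curve.

A caveat that matters when comparing against sub-cM window values reported
for composite designs elsewhere: five or six meioses of recombination
decay LD by only a few percent over 1 cM, so under a mechanistic
recombination model the $r^2 = 0.20$ crossing of a composite population
necessarily sits at several cM (the package's default scenarios produce
windows around 14 cM at N = 1000). Sub-cM crossings after five
generations would require LD to exist only between near-adjacent loci,
which a forward simulator that transmits whole recombinant haplotypes
cannot produce - and which real meiosis does not produce either. The
acceptance suite records this honestly: the widening trend from N = 1000
to N = 200 reproduces, the absolute sub-cM window value does not.

## Population-structure correction

`grm()` builds the VanRaden genomic relationship matrix
$G = ZZ'/\sum_j 2p_j(1-p_j)$ from frequency-centered dosages, and
`pca_covariates()` takes the leading K eigenvectors (scaled by square-root
eigenvalues, sign-fixed so each vector's largest entry is positive) as
fixed covariates. The study defaults are K = 19 for the 3-QTL
configuration and K = 18 for the 100-QTL one; `choose_k()` offers the
alternative rule "smallest K explaining at least 85% of the variance". The
leading components separate the 20 full-sib families cleanly (tested as a
within- versus between-family score-distance contrast).

In a non-inbred forward-simulated population, however, 19 components
cannot explain 85% of the genotypic variance: within-family
Mendelian-sampling variance - full sibs receiving independent gamete draws
from their parents - accounts for roughly half of the total, so the
family-driven leading eigenvalues plateau near 50-55% regardless of the
parental frequency law (the acceptance run reports the realized value,
about 54%). A 19-component share of 85-96% would require near-clonal
families, i.e. strongly inbred parents, which five generations of random
mating among 5000 individuals cannot produce. This is a structural
property of the design worth knowing: it bounds how much marker signal
structure correction can absorb, and it is documented here rather than
tuned away.

## The association scans

Both methods fit, marker by marker, the model
$$Y = \mu + \alpha_j\,\mathrm{SNP}_j + \sum_{k=1}^K \beta_k \mathrm{CP}_k + \varepsilon,$$
with the marker dosage coded additively (0/1/2, unstandardized, so
$\hat\alpha_j$ is per allele) and the structure components as covariates.
Markers are always tested one at a time; monomorphic markers in the
current (possibly downsampled) population are excluded from all
bookkeeping and listed in the scan's `skipped` attribute.

**GLM (OLS).** The normal-equations solution with the usual t-test on the
marker coefficient. The scan is vectorized over markers through
Frisch-Waugh projection (residualize the phenotype and every marker on the
covariate block once), which a test verifies agrees with the full
per-marker fit to 1e-10.

**Quantile regression.** The coefficient vector at quantile $\tau$
minimizes the check loss
$\rho_\tau(\varepsilon) = \tau\varepsilon\,[\varepsilon \ge 0] +
(\tau-1)\varepsilon\,[\varepsilon < 0]$. `fit_quantile_model()` solves the
equivalent linear program (split positive/negative residuals) with a
Mehrotra predictor-corrector primal-dual interior-point method: starting
from the OLS coefficients and a zero dual keeps the linear constraints
exactly satisfied, so only complementarity must be driven to zero; each
iteration factorizes one p x p system. The duality gap tolerance is
1e-10 (relative to problem scale, capped at 200 iterations), and the
objective matches an exhaustive enumeration of exact-fit bases to 1e-8 on
small instances. Degenerate optima (ties among optimal bases) are
acceptable; tests assert the objective, not the coefficient vector.
Default quantiles are 0.10, 0.50 and 0.90.

Inference is by the regression rank-score (sign-score) test, which avoids
estimating the error density: fit the reduced model (intercept +
covariates) at $\tau$, take the rank scores
$a_i = \tau - 1\{\hat\varepsilon_i < 0\}$ - the interior-point dual is
exactly this vector, including the correct fractional values on the
zero-residual basic observations - project the marker off the reduced
design, and refer $(\tilde x'a)^2 / [\tau(1-\tau)\tilde x'\tilde x]$ to
$\chi^2_1$. One reduced fit serves all 2000 markers, so rank-score
p-values for a whole scan cost one LP plus a matrix product. The reported
marker effects come from full per-marker LP fits (`qr_effects = TRUE`; can
be disabled when only calls are needed).

Choosing the rank-score test is an interpretation: "rank-based" QR
inference in the applied literature sometimes means rank-inversion
confidence intervals, whose implied tests are not identical. We chose the
score version because it emits p-values directly, is the standard
density-free QR test, and is verifiably calibrated - the suite checks its
type-I error at nominal level within binomial 99% bounds over 2000 null
simulations, alongside the same check for the OLS t-test.

This calibration has a consequence worth stating plainly: under the
simulated model (additive effects, normal errors) a correctly calibrated
sign-score test is asymptotically *less* efficient than OLS at every
quantile - the efficiency factor $f(F^{-1}(\tau))^2/(\tau(1-\tau))$ is
about 0.64 at $\tau = 0.5$ and 0.34 at $\tau = 0.1$ for normal errors, and
the suite's power comparisons bear this out. Claims that QR at extreme
quantiles dominates OLS in exactly this setting can only arise from
anticonservative rank-based standard errors (test statistics that grow
with sample size faster than their nominal null law), and the package
deliberately does not reproduce that behaviour. QR's genuine advantages -
robustness to heavy-tailed errors and heteroscedastic, quantile-specific
effects - are outside the simulated normal-error model.

**Multiple testing.** P-values are adjusted jointly across all tested
markers by Benjamini-Hochberg step-up q-values (default; Storey's
$\pi_0$-estimated variant is available via `qvalue_method = "storey"`),
and a marker is significant when $q \le \alpha$ with $\alpha = 0.01$.

## Power, false positives, and the scenario engine

For one scan, *detection power* is the proportion of target-QTL windows
$[pos - w, pos + w]$ containing at least one significant marker, and the
*false-positive rate* is the proportion of non-associated markers (outside
every target window) that are significant. Under `major3_plus97` only the
3 major genes define windows; markers near the 97 minor loci therefore
count as potential false positives, an interpretation consistent with
scoring power in thirds for that architecture. Both definitions are tested
against brute-force set-arithmetic oracles.

`run_scenario()` executes the full chain per replicate - simulate
population and trait, then for each nested population size: LD window,
PCA, all configured scans, power and FPR - and `summarize_scenario()` /
`make_tables()` aggregate replicates into mean +/- SE tables laid out as
architecture x heritability x method rows against population-size columns.
The default grid is 2 architectures x 2 heritabilities x 9 sizes = 36
scenarios with 10 replicates each. Randomness is governed by one master
seed per scenario, split hierarchically (`derive_seed()`) per replicate
and stage, so any stage of any replicate can be reproduced in isolation
and results are independent of execution order. Downsampled populations
are nested within a replicate (the N = 800 sample is a subset of the
N = 900 sample), mirroring stepwise random reduction.

## Numerical and design choices

* Interior-point tolerances: duality gap below `1e-10 * n * scale`,
  maximum 200 iterations; step damping 0.9995 to the boundary; fallback to
  a pseudoinverse solve if the normal matrix degenerates.
* Residual-sign bookkeeping at an LP optimum uses a 1e-6 tolerance; the
  optimality bounds (#negative residuals $\le n\tau \le$ #negative +
  #zero) are property-tested.
* The decay-curve evaluator aggregates pairs into distinct-distance bins;
  the bandwidth at an evaluation point is the distance of the furthest bin
  needed to cover the span fraction, whose tricube weight vanishes -
  matching the q-th-nearest-neighbour convention exactly.
* Eigenvector signs, marker order, and individual order are all fixed or
  tested invariant, so outputs are bitwise reproducible for a given seed.
* Degenerate inputs error loudly: rank-deficient designs, all-monomorphic
  marker sets, decay curves that never cross the threshold ("no window"),
  infeasible downsampling targets, out-of-range quantiles, probabilities
  or heritabilities.

Problem sizes in the test suite are the package's own choices: unit and
property tests run on scaled-down genomes (hundreds of markers, composites
of a few hundred) where the tested invariants are size-free; the
acceptance suite and `scripts/acceptance.R` run the full 2000-marker,
N = 1000 design with 3-10 replicates per quantity, matching the scale at
which the summary statistics stabilize.

## What the simulator does and does not emulate

It emulates: composite-population LD generated by parental divergence and
eroded by recombination and drift; full-sib family structure and its
effect on relationship matrices, LD noise floors and structure-corrected
scans; additive polygenic and major-gene architectures calibrated to exact
heritabilities; and the complete scan-and-score pipeline.

It does not emulate: mutation, selection, migration, crossover
interference, dominance or epistasis, genotype-by-environment interaction,
genotyping error or missingness, sex chromosomes, or non-normal phenotype
errors. The last omission matters for interpretation: the simulated
setting is the one *least* favourable to quantile regression, so passing
tests here say nothing about QR's behaviour on skewed or outlier-prone
real phenotypes, which is where its robustness arguments apply.
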