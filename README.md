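# qrgwas

Power of QTL detection by quantile-regression GWAS versus the general
linear model, studied by simulation on composite breeding populations.

Genome-wide association studies in breeding programs often have few
genotyped and phenotyped individuals. `qrgwas` is built to study, under
fully known ground truth, how two single-marker scan methods behave as the
population shrinks:

- **GLM**: ordinary least squares on the model
  `Y = mu + alpha_j SNP_j + sum_k beta_k CP_k + e`, with the leading
  principal components (CP) of the VanRaden genomic relationship matrix as
  fixed population-structure covariates and the usual t-test on the marker
  effect `alpha_j`;
- **QR**: quantile regression of the same model at quantiles
  tau = 0.10, 0.50, 0.90, estimated by minimizing the check loss
  `rho_tau(e) = tau*e` for `e >= 0`, `(tau-1)*e` otherwise — solved as a
  linear program by a purpose-built primal-dual interior-point method —
  with p-values from the density-free regression rank-score test.

Everything the study needs is generated inside the package: a forward
simulator of an advanced-generation composite (two diverged parental
populations crossed, 5 generations of random mating under Haldane
recombination, a study sample of 20 full-sib families of 50), additive
trait architectures of 100 small-effect QTLs or 3 major genes (50% of the
genetic variance) plus 97 minor loci at heritabilities 0.30/0.50,
LD-decay-calibrated QTL detection windows (local-polynomial fit of
pairwise r² against distance, window at the r² = 0.20 crossing),
FDR-controlled significance calls (q ≤ 0.01), and replicate-wise QTL
detection power and false-positive rates across population sizes
1000 → 200.

## Worked example

A scaled-down study cell (4 chromosomes, 240 markers, 10 families of 30,
3 major genes, h² = 0.5) from simulation to power score:

```r
library(qrgwas)

cfg <- sim_config(
  n_chromosomes = 4, chrom_length_cM = 60, markers_per_chrom = 60,
  n_qtl = 20, composite_size = 600, n_generations = 3,
  n_families_base = 60, n_families = 10, family_size = 30
)
sim <- simulate_study_population("major3_plus97", cfg, seed = 42)
sim$population
#> <population> 300 individuals x 260 loci (generation 4, 10 families)

trait <- simulate_trait(sim$population, sim$map, h2 = 0.5, seed = 42)
trait
#> <trait_model> major3_plus97; h2 target 0.5; var(g) = 24.12, sigma2_e = 24.12; n = 300
```

`var(g) = sigma2_e` is the h² = 0.5 calibration doing its job. Next the
LD-based detection windows and the structure covariates:

```r
pairs <- pairwise_r2(sim$population)
w <- window_distance(fit_decay_curve(pairs), threshold = 0.2)
w
#> [1] 11.81333
assoc <- qtl_marker_association(sim$map, w,
                                targets = dplyr::filter(trait$effects, is_major))
assoc
#> <association_map> w = 11.81 cM; 44/240 markers associated across 3 QTL windows

pca <- pca_covariates(grm(sim$population), K = 9,
                      family_id = sim$population$family_id)
pca
#> <structure_pca> K = 9 components; cumulative variance 70.5%
```

The fitted decay curve crosses r² = 0.20 at 11.8 cM, so each major gene
gets a ±11.8 cM window; a QTL counts as detected if any marker in its
window is significant. Now both scans and their scores:

```r
y <- trait$phenotypes$phenotype
scan_glm <- gwas_scan(sim$population, y, pca, method = "glm")
scan_qr  <- gwas_scan(sim$population, y, pca, method = "qr", tau = 0.1)

c(power_glm = detection_power(scan_glm, assoc),
  fpr_glm   = false_positive_rate(scan_glm, assoc),
  power_qr  = detection_power(scan_qr, assoc),
  fpr_qr    = false_positive_rate(scan_qr, assoc))
#> power_glm   fpr_glm  power_qr    fpr_qr
#> 0.3333333 0.0000000 0.0000000 0.0000000

dplyr::arrange(tidy(scan_glm), qvalue) |> head(3)
#> # A tibble: 3 × 11
#>   locus_id chrom pos_cM method   tau effect    se statistic       pvalue  qvalue
#>   <chr>    <int>  <dbl> <chr>  <dbl>  <dbl> <dbl>     <dbl>        <dbl>   <dbl>
#> 1 M1_20        1     19 glm       NA  -4.30 0.741     -5.80 0.0000000171 4.10e-6
#> 2 M1_21        1     20 glm       NA   4.16 0.737      5.65 0.0000000393 4.72e-6
#> 3 M1_19        1     18 glm       NA  -4.02 0.755     -5.32 0.000000208  1.66e-5
```

The GLM finds one of the three major-gene windows (a tight cluster of
significant markers at 18-21 cM on chromosome 1, q ≤ 0.01) with no false
positives; the calibrated rank-score QR scan at tau = 0.10 finds none at
this sample size — under normal errors a correctly calibrated sign-score
test is less efficient than OLS, one of the package's central, deliberate
findings (see the methods vignette).

Full study grids run through `scenario_spec()` / `run_scenario()` /
`make_tables()`, which emit the power and false-positive-rate tables
(mean ± SE over replicates, methods × population sizes) as CSV.
`autoplot()` methods cover LD decay, Manhattan plots, PCA scores and
power curves.

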