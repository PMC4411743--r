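# gxekit

Gene-environment interaction (G×E) analysis for polygenic traits. Complex
disease risk is spread over many variants of tiny individual effect, so
asking whether *one* candidate SNP interacts with an exposure is
statistically hopeless; gxekit instead aggregates the genome-wide signal
and asks whether that aggregate genetic effect depends on the environment.
It is aimed at statistical geneticists and epidemiologists with
genome-wide genotypes (PLINK bed/bim/fam), an environmental measure, and
either external GWAS summary statistics or a sample large enough for
variance-component estimation.

Two frameworks are implemented end to end:

**1. Risk profiling.** Each target individual gets a genomic risk profile
score from independent discovery-sample effect sizes,

    G_i = (1 / |L_i|) * sum_{j in L_i} x_ij * beta_j,

(the effect-weighted risk-allele count averaged over that individual's
non-missing loci), and G×E is tested through nested logistic models

    logit P(Y=1) = b0 [+ covariates] [+ bE*E] [+ bG*G] [+ bGE*G*E]

compared by likelihood-ratio tests, with decile odds ratios for risk
stratification. Multiple score partitions (e.g. by functional annotation)
give one G and one G×E term each.

**2. Mixed linear model.** With individual-level data, the phenotype is
modelled as y = Xb + g + ge + e with Var(y) = s2_g*A_g + s2_ge*A_ge +
s2_e*I, where A_g is the SNP-derived genetic relationship matrix and A_ge
keeps A_g for same-environment pairs and zeroes it otherwise (binary E;
continuous exposures use A_g ∘ zz'). Components are estimated by
average-information REML and tested by likelihood-ratio tests (boundary
mixture null). A bivariate variant treats the trait in two environments as
two traits; a cross-environment genetic correlation r_g significantly
below 1 indicates G×E and is robust to different scales or ascertainment
in the two environments.

A cohort simulator with known architecture (`simulate_cohort()`,
`simulate_discovery()`) underpins all verification, and PLINK 1 binary
genotypes, GCTA binary GRMs and delimited phenotype/environment/summary
tables are read and written natively. There is also a thin command line
(`inst/exec/gxekit`) with subcommands `simulate`, `score`, `profile`,
`grm`, `gxe-grm`, `reml`, `reml-bivar`.

## Worked example

Simulate a target cohort with a real interaction, score it with weights
from an independent discovery GWAS, and run both frameworks:

```r
library(gxekit)

target <- simulate_cohort(
  n = 2000, m = 1500, sigma2_g = 0.35, sigma2_ge = 0.15, sigma2_e = 0.5,
  env = "binary", trait = "binary", prevalence = 0.3,
  interaction = "amplification",   # genetic effects stronger when exposed
  id_prefix = "tg", seed = 42)
sumstats <- simulate_discovery(target, n_discovery = 8000, seed = 43)

scores <- compute_grps(target$genotypes,
                       match_alleles(target$genotypes, sumstats))
profile <- fit_nested_models(target$phenotype, scores, target$environment)
profile
#> <gxe_profile> binomial nested models, n = 2000
#> # A tibble: 3 x 6
#>   term       statistic    df  p_value r2_nagelkerke_increment p_bonferroni
#>   <chr>          <dbl> <int>    <dbl>                   <dbl>        <dbl>
#> 1 env             13.1     1 2.93e- 4                 0.00938    NA
#> 2 grps           162.      1 3.42e-37                 0.111      NA
#> 3 grps_x_env      40.3     1 2.23e-10                 0.0262      2.23e-10
```

Each row is the likelihood-ratio test of adding that term to the previous
model: the score is strongly associated (the discovery sample is large),
and the score-by-environment product adds a decisive test on top of the
main effects — the simulated interaction is detected. Risk stratification
by score decile:

```r
decile_odds_ratios(target$phenotype, scores)[c(1, 10), ]
#> # A tibble: 2 x 9
#>   decile     n cases controls   odds odds_ratio ci_lower ci_upper degenerate
#>    <int> <int> <dbl>    <dbl>  <dbl>      <dbl>    <dbl>    <dbl> <lgl>
#> 1      1   200    16      184 0.0870       1      0.486     2.06 FALSE
#> 2     10   200   111       89 1.25        14.3    8.01     25.7  FALSE
```

Individuals in the top score decile carry about 14 times the disease odds
of the bottom decile. The variance-component route on the same cohort:

```r
A  <- compute_grm(target$genotypes)
ge <- build_ge_matrix(A, target$environment)
fit <- fit_univariate(vc_model(target$phenotype, list(g = A, ge = ge),
                               env = target$environment))
tidy(fit)
#> # A tibble: 3 x 6
#>   component estimate      se proportion prop_se at_boundary
#>   <chr>        <dbl>   <dbl>      <dbl>   <dbl> <lgl>
#> 1 g           0.0348 0.00882     0.172   0.0425 FALSE
#> 2 ge          0.0104 0.0111      0.0515  0.0549 FALSE
#> 3 residual    0.157  0.00885     0.776   0.0407 FALSE
```

Estimates here are on the observed 0/1 disease scale, so they are much
smaller than the liability-scale inputs and blunt to detect at this
sample size (`lrt_component(fit, reduced)` gives p = 0.17 for the
interaction component); that is expected, and it is why for disease
traits the bivariate cross-environment test (`fit_bivariate()`), which is
unaffected by scale and ascertainment differences between environments,
is the recommended G×E criterion.

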