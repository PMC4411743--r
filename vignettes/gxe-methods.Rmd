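---
title: "Methods: polygenic gene-environment interaction in gxekit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: polygenic gene-environment interaction in gxekit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

gxekit implements two complementary strategies for detecting
gene-environment interaction (G×E) when the genetic signal is polygenic:
many variants of individually negligible effect. Single-variant interaction
tests are then hopeless — the prior probability that one candidate SNP
interacts with one exposure is tiny — so both strategies aggregate the
genome-wide signal first and ask whether that *aggregate* genetic effect
depends on the environment.

## 1. Risk-profiling framework

A genomic risk profile score (GRPS) summarises an individual's genetic
liability as the effect-weighted count of risk alleles, averaged over the
loci available for that individual:

$$G_i = \frac{1}{|L_i|} \sum_{j \in L_i} x_{ij}\,\hat\beta_j,$$

where $x_{ij} \in \{0,1,2\}$ counts the scored allele and $\hat\beta_j$ is
the effect estimated in an independent *discovery* GWAS (betas from linear
regression or log odds ratios from logistic regression; odds-ratio input is
log-transformed so scores stay additive). Two design rules matter:

* **No sample overlap.** Individuals scored in the target sample must not
  have contributed to the discovery GWAS, otherwise the score overfits and
  association is inflated. `compute_grps()` warns when supplied discovery
  ids intersect the target, and `simulate_discovery()` refuses to generate
  overlapping cohorts.
* **Allele bookkeeping before weighting.** `match_alleles()` resolves each
  shared variant as a direct match, an effect-allele flip (weight negated),
  or a strand flip via base complements; palindromic A/T and C/G variants
  are excluded by default because their strand cannot be resolved.

Per-individual averaging over *non-missing* loci is used as the
denominator (the convention of the standard scoring tools); missing
genotypes drop out of numerator and denominator, with mean-dosage
imputation available as an option. Scores may be computed inside SNP
partitions (functional annotation, physical position) to give one genetic
term per hypothesis.

For a disease trait the interaction test is a sequence of nested logistic
models,

$$\text{logit}\,P(Y_i = 1) = \beta_0 + \mathbf{c}_i'\boldsymbol\gamma
  \;[+\; \beta_E E_i] \;[+\; \beta_G G_i] \;[+\; \beta_{GE} G_i E_i],$$

fitted by maximum likelihood and compared by likelihood-ratio tests with
degrees of freedom equal to the columns added at each step (one $G$ and one
$G\times E$ column per partition). Significant main effects of $G$ and $E$
already imply interaction on the observed disease scale; the product term
addresses interaction on the underlying liability. We report Nagelkerke
$R^2$ increments per step, and for quantitative phenotypes the analogous
linear-model nesting with F tests — an extension beyond the disease-trait
setting, clearly labelled as such. Decile odds ratios
(`decile_odds_ratios()`) display risk stratification: individuals are
ranked on the score, split into ten near-equal groups with deterministic
tie-breaking, and each decile's disease odds are compared with the bottom
decile (Woolf confidence intervals; zero cells flagged rather than
smoothed).

Interaction columns are built from the z-standardised score by default.
The likelihood-ratio statistics are invariant to affine rescaling of the
score and of a continuous environment (verified by test), so this choice
affects only coefficient readability. Across partitions we report raw
interaction p-values plus a Bonferroni adjustment over the number of
interaction terms; nothing fancier, because the partitions are
user-defined hypotheses.

**Separation.** Small or strongly stratified samples can separate
perfectly, sending logistic estimates to infinity. Fits are done by
iteratively reweighted least squares (`glm.fit`); on detected separation or
non-convergence the fit falls back to Firth's bias-reduced logistic
regression (score adjusted by hat values, penalised log-likelihood
$\ell + \tfrac12 \log|X'WX|$) with a warning. Mixing penalised and
unpenalised likelihoods in one nested sequence is avoided: the fallback
applies per model fit and is flagged on the result.

## 2. Mixed-linear-model framework

The variance-component model treats aggregate SNP effects as random:

$$y = X\beta + g + ge + \varepsilon,\qquad
\operatorname{Var}(y) = \sigma^2_g A_g + \sigma^2_{ge} A_{ge} +
\sigma^2_e I,$$

with $A_g$ the genetic relationship matrix estimated from all SNPs,

$$A_{g,jk} = \frac{1}{m_{jk}} \sum_i
\frac{(x_{ij} - 2p_i)(x_{ik} - 2p_i)}{2p_i(1-p_i)},$$

allele frequencies estimated in-sample, denominators counting the loci
non-missing in both members of each pair, variants below the MAF filter
(default 0.01) and monomorphic variants excluded because the denominator
degenerates. The same formula is used on the diagonal, so the diagonal
averages 1 under Hardy-Weinberg equilibrium.

The interaction relationship matrix encodes "genetic similarity counts
only within an environment":

* binary or categorical exposure: $A_{ge,jk} = A_{g,jk}$ if $e_j = e_k$,
  else $0$; the diagonal is always retained (an individual shares its own
  environment). For more than two categories the same-level rule
  generalises naturally and is what we implement.
* continuous exposure: $A_{ge} = A_g \circ zz'$ with $z$ the environment
  standardised to mean 0, variance 1 — the random-regression
  (reaction-norm) form. With a ±1 coding this reduces to the binary rule
  only up to scale, so the two conventions are not interchangeable.

The binary-E matrix is a Schur product of a PSD matrix with a block
indicator and is therefore PSD (verified numerically across random
fixtures). $A_{ge}$ is used unscaled; a switch to rescale its mean
diagonal to 1 exists but defaults off, since the masking rule is the
model definition. Whenever $A_{ge}$ is fitted, the environment main effect
is included as a *fixed* effect: the random-effects equation omits fixed
terms, but leaving the E main effect out would let it leak into the
interaction component.

**Estimation.** Restricted maximum likelihood via average-information (AI)
REML: the restricted log-likelihood

$$\ell = -\tfrac12\left[(n-p)\log 2\pi + \log|V| + \log|X'V^{-1}X| +
y'Py\right]$$

is maximised with Newton-type steps using the average-information matrix
$\mathrm{AI}_{jk} = \tfrac12 y'P\dot V_j P \dot V_k Py$, step-halving when a
proposal does not increase $\ell$ or leaves the positive-definite cone, an
EM-style rescue step when no halved AI step helps, and an active-set floor
(at $10^{-6}$ of the phenotypic variance) keeping variance components
non-negative; parameters pinned at the floor with downhill gradients are
dropped from the AI system for that iteration. Convergence requires a
relative log-likelihood change below $10^{-8}$ on a full AI step; the
iteration cap is 200, and non-convergence is an error carrying the trace.
Initialisation is deterministic (phenotypic variance split equally across
components), so fits are bit-reproducible for fixed input. Standard errors
come from the inverse AI matrix at the optimum; variance *proportions* get
delta-method standard errors. The engine also accepts a smooth
reparametrisation of the structure coefficients (coefficients plus
Jacobian), which the bivariate $r_g = 1$ constraint uses.

Component significance uses likelihood-ratio tests. Dropping a single
variance component tests a null on the boundary of the parameter space, so
the default reference is the equal mixture
$\tfrac12\chi^2_0 + \tfrac12\chi^2_1$; the plain $\chi^2_1$ is available by
flag. Binary disease phenotypes are analysed on the observed 0/1 scale;
no liability transformation of the estimates is attempted, because
per-environment disease prevalences make transformed per-environment
heritabilities hard to interpret — for disease traits the bivariate test
below is the recommended G×E criterion.

**Bivariate two-environment model.** With a binary exposure and each
individual observed in one environment, the trait in the two environments
is treated as two traits. Ordering individuals by group,

$$V = \begin{pmatrix}
\sigma^2_{g1} A_{11} + \sigma^2_{e1} I &
r_g \sigma_{g1}\sigma_{g2} A_{12}\\
r_g \sigma_{g1}\sigma_{g2} A_{21} &
\sigma^2_{g2} A_{22} + \sigma^2_{e2} I
\end{pmatrix},$$

with no residual cross-covariance (the groups are disjoint people) and
per-group fixed means. The free fit estimates the genetic covariance as its
own parameter; $r_g$ is the ratio $c_{12}/(\sigma_{g1}\sigma_{g2})$ with a
delta-method standard error. Constrained fits at $r_g = 1$
(parametrised as $c_{12} = \sqrt{\sigma^2_{g1}\sigma^2_{g2}}$ via the
Jacobian interface) and $r_g = 0$ (cross-block dropped) give
likelihood-ratio tests with one degree of freedom. $r_g$ significantly
below one indicates G×E; heritabilities are *not* forced equal across
environments, and when they differ an $r_g$ of one does not rule out a
scale effect — both $r_g$ tests and the per-group variance ratios are
reported, and the verdict is left to the analyst. If a group's genetic
variance estimate sits on the zero boundary, $r_g$ is undefined and
flagged rather than reported.

**Scale effects.** Interaction variance that a monotone transformation of
the phenotype removes is a scale effect, not biological interaction.
`transform_phenotype()` offers rank-inverse-normal (Blom offsets, ties
averaged) and log transforms so the interaction estimate can be compared
before and after transformation; rank-based transforms are invariant to
any monotone rescaling, which is the property that makes the comparison
meaningful. Not every scale effect is removable by transformation, so a
surviving interaction after transformation is supportive, not conclusive.

## 3. What the simulator generates — and what it does not

`simulate_cohort()` is the package's verification surface. Genotypes are
hard calls at independent loci: per-variant allele frequencies uniform in
the configured MAF range (default 0.05–0.5), dosages as two independent
allele draws (Hardy-Weinberg). Every variant is causal with a normal
effect on the standardised-dosage scale — the default polygenic
architecture in this field; no other effect-size distribution is offered.
Each generated component (genetic, interaction, residual) is rescaled to
hit its configured variance *exactly* in-sample, so estimator bias can be
read directly against the configured truth rather than against a noisy
realised value.

The interaction architecture deserves a precise statement. For a binary
(or categorical) environment the interaction genetic value is drawn
**independently per environment level**: $ge_i = (Z\gamma^{(k)})_i$ for
individual $i$ in level $k$, with independent $\gamma^{(k)}$ per level,
jointly rescaled to $\sigma^2_{ge}$. This makes
$\operatorname{Cov}(ge) = \sigma^2_{ge}\,A_g \circ M$ with $M$ the
same-environment indicator — exactly the masked $A_{ge}$ the GREML model
fits. The superficially attractive alternative, multiplying one genetic
value by the centred exposure, instead induces
$\operatorname{Cov}(ge) = \sigma^2_{ge}(2A_g\circ M - A_g)$, which is *not*
the masked matrix: fitting $A_{ge}$ to such data is biased by construction
(the genetic component absorbs $-\sigma^2_{ge}$ and the interaction
component doubles), so we reserve the centred-multiplier form for the
continuous-environment generator, where it exactly matches
$A_{ge} = A_g \circ zz'$. A separate `interaction = "amplification"`
switch makes the interaction value proportional to the main genetic value
— a pure scale effect — for exercising the transformation check.

Binary traits threshold the liability at the quantile implied by the
configured prevalence, with optional case enrichment afterwards for
profiling experiments. `simulate_discovery()` replays the same true
effects in a fresh cohort and estimates per-variant marginal regression
betas, giving a complete two-sample scoring rehearsal.

Deliberately absent: linkage disequilibrium, population structure,
dominance and higher-order epistasis, genotyping error, and ascertainment
of the discovery GWAS. Passing tests therefore demonstrate correctness of
the estimators under the stated generative model, not robustness to the
confounders of real cohorts — in real data, LD between scored SNPs and
stratification-driven score-environment correlation are the first things
to worry about.

## 4. Verification scales and numerical choices

The test suite checks, at fixed seeds chosen in advance:

* agreement of the likelihood evaluation with an independent
  dense-algebra implementation ($10^{-8}$) and of the AI-REML optimum with
  a grid-plus-refinement maximisation ($10^{-4}$) on n = 200 fixtures;
* recovery of $(\sigma^2_g, \sigma^2_{ge}, \sigma^2_e) = (0.3, 0.2, 0.5)$
  with binary exposure of prevalence 0.5 at n = 2000, m = 5000 over 20
  replicates (mean absolute bias ≤ 0.05 per component);
* type-I error of the interaction tests at $\alpha = 0.05$: 1000
  profiling replicates at n = 2000, and 200 REML replicates at n = 1000
  (m = 1000, $\sigma^2_g = 0.3$) against the boundary mixture;
* bivariate discrimination at n = 1000 per environment, m = 2000,
  per-environment heritability 0.5: shared effects give mean
  $\hat r_g \ge 0.9$ with $r_g = 1$ rarely rejected, independent
  per-environment effects give $r_g = 1$ rejected in ≥ 90% of replicates;
* exact masking, PSD-ness of binary-E $A_{ge}$, GRM diagonal behaviour
  under Hardy-Weinberg, bit-exact PLINK roundtrips, float32-exact GCTA GRM
  roundtrips, and ≥ 80% detection of the genetic term in a full two-sample
  scoring pipeline (discovery n = 5000, target n = 1000,
  $\sigma^2_g = 0.5$).

Sizes not pinned by the criteria (m for the REML null and bivariate
studies, the bivariate variance split) were fixed once as realistic
polygenic settings before the studies were run. `scripts/acceptance.R`
re-runs scaled-down versions of the same computations end to end and
writes the resulting quantities as JSON.

Numerical conventions worth knowing: the REML log-likelihood includes its
constant $-\tfrac12(n-p)\log 2\pi$; GRM persistence is float32 (the GCTA
binary format), so roundtrips are exact only to single precision; CLI TSV
output uses six significant digits; decile ties break by input order;
score standardisation uses the sample standard deviation. Known
limitations: dense $O(n^2)$ memory and $O(n^3)$ per-iteration REML cost
cap practical sample sizes around the tens of thousands on one machine;
the bivariate model handles exactly two environments; no LD-aware score
re-weighting or clumping is provided — weights are taken as given.
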