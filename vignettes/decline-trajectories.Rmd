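---
title: "Modelling regional brain-volume decline with latent growth curves"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Modelling regional brain-volume decline with latent growth curves}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

`lgctraj` implements a longitudinal analysis of regional brain-volume
decline in healthy aging: univariate and bivariate random-slope growth
models, influence-based quality control, 20-year decline extrapolation with
bootstrap uncertainty, and principal component analysis of person-specific
slopes. This vignette explains the models, the choices behind the defaults,
and what the accompanying synthetic-cohort generator does and does not
emulate.

## The univariate growth model

Each region's volume is followed over up to four planned waves (0, 1, 2 and
4 years after baseline, with a minority of subjects measured near 3 years).
Age enters twice, deliberately: the **entry-age** (age at the baseline
scan) carries the between-subject information, and the **time in study**
carries the within-subject change. Conflating the two lets between-subject
level differences contaminate the estimated change; separating them is the
backbone of every model here.

For subject $i$, region volume $y_{ij}$ at time $t_{ij}$ (years since
baseline):

$$
y_{ij} = \beta_0 + \beta_a a_i + \beta_{a2} a_i^2 + \beta_v v_i
  + (\beta_s + \beta_{sa} a_i + \beta_{sv} v_i)\, t_{ij}
  + u_{0i} + u_{1i} t_{ij} + e_{ij},
$$

with $a_i$ the entry-age centered at 65, $v_i$ the intracranial volume
(ICV) standardized after grand-mean centering,
$(u_{0i}, u_{1i}) \sim N(0, G)$ and $e_{ij} \sim N(0, \sigma^2)$
independent. Because responses are first rescaled to percent of the
region's age-65 volume (below), $\beta_s$ is the annual percent change of a
65-year-old with average head size, and $\beta_{sa}$ tells whether decline
accelerates with later study entry. The random-slope SD
$\sqrt{G_{22}}$ quantifies how much individuals genuinely differ in their
rate of decline — the quantity of main scientific interest.

Fitting is full-information maximum likelihood via `lme4`; subjects
contribute all and only their observed waves, which is valid under the
missing-at-random assumption. The fit object also carries each subject's
marginal log-likelihood contribution and the conditional (shrunken)
distribution of $(u_{0i}, u_{1i})$, both computed from the closed-form
multivariate-normal expressions; the per-subject contributions sum to the
model log-likelihood, which doubles as an internal consistency check.

**ML versus REML.** The default is ML so that likelihood-ratio tests —
between nested fixed-effect structures and on the random-slope variance —
compare likelihoods of the same form. ML variance components carry the
usual small downward bias at $n \approx 231$ (about 4% on the random-slope
SD in our simulations); when the variance components themselves are the
estimand, as in the parameter-recovery checks of the test suite, the
`reml = TRUE` flag is the standard remedy and is what those checks use.

**Random-slope test.** Removing the random slope also removes the
intercept-slope covariance and places a variance at the boundary of its
parameter space, so twice the log-likelihood difference is referred to the
50:50 mixture of $\chi^2(1)$ and $\chi^2(2)$. At statistic 0 the p-value
is 1. Simulations with a truly zero slope variance give an empirical size
of about 0.06 at the nominal 0.05 under this reference (100 replicates at
study scale).

**Sex differences.** The sex-extended model adds a male indicator and its
interactions with entry-age, entry-age², time, and time × entry-age; the
2-df likelihood-ratio test drops the two sex-by-slope terms. "Sex ×
entry-age squared" is implemented as the interaction of sex with the
quadratic age term — for a 0/1 indicator the literal square of the product
is the same column.

## Percent-of-intercept scaling

Regions differ enormously in size, so raw mm³ slopes are not comparable.
Each region is divided by its fitted population volume at entry-age 65 and
average ICV — the intercept of a random-slope model with level covariates
entry-age, entry-age², and ICV — and multiplied by 100. All downstream
slopes are then "percent of the age-65 volume per year". The fitted
intercept is estimated from the sample, so recovered coefficients carry a
small multiplicative wobble of order the intercept's standard error;
rescaling an already-scaled cohort refits an intercept of ~100 and is
idempotent to that tolerance.

## Time binning

Latent growth curve software wants a small set of shared slope loadings,
not one loading per subject. Observed times are therefore clustered by an
exact dynamic program for one-dimensional k-median: the optimal partition
of sorted times into $k$ contiguous clusters minimizing total L1 distance
to the cluster medians (an optimal L1 partition is always contiguous, so
the DP is exact; the suite checks it against exhaustive search). The bin
value is the exact cluster median, not a rounded representative. When $k$
is not given, the smallest $k$ whose cost falls below 1% of the one-cluster
cost is used — this reproduces "narrow bins" behaviour without committing
to a fixed count, and both $k$ and the fraction are configurable. Mixed
models keep using the exact times; only latent-growth fitting (the
bivariate sampler, and influence screening by convention) uses the binned
loadings.

## Influence-based quality control

MRI segmentation occasionally fails in ways that produce influential
trajectories. For each subject the package computes Cook's distance on the
fixed effects (exact case-deletion refits, or a faster one-step
approximation that holds the variance components at their full-data
values) and the subject's log-likelihood contribution. A subject is
excluded when Cook's distance exceeds 0.5 with a contribution below −7.5,
or Cook's distance exceeds 1 with a contribution below −4. The thresholds
are conventional defaults chosen by inspection, not optimized, and are
configurable; the likelihood-contribution scale depends on the data
scaling, so they should be revisited if the percent scaling is not used.
The one-step approximation tracks the exact refit within 20% for the large
majority of subjects but can deviate more for the single most influential
one — use `method = "refit"` when the decision is borderline.

## 20-year extrapolation and pairwise comparison

The expected loss from age 65 to 85 refreshes the annual slope every four
years as the cohort effectively ages through the entry-age dimension:

$$
\mathrm{loss}_{20} = \sum_{k=0}^{4} 4\,(\beta_s + \beta_{sa}\cdot 4k)
  = 20\beta_s + 160\beta_{sa}.
$$

Uncertainty comes from a nonparametric bootstrap that resamples whole
subjects (preserving within-subject dependence), refits every region's
model per replicate, and recomputes $\mathrm{loss}_{20}$. Intervals are
95% percentile intervals. For each ordered pair of regions the
**pairwise mass** is the fraction of replicates in which the first
region's loss magnitude exceeds the second's; exact ties count half, so
the matrix and its transpose always sum to one. Note a subtlety checked in
the test suite: for two regions generated with identical parameters, a
*single* cohort's pairwise mass is approximately uniform — the bootstrap
faithfully tracks whichever region happens to decline faster in that
sample — and only its expectation over cohort replications is ½.

## The bivariate Bayesian growth model

To learn whether fast decliners in one region are fast decliners in
another, pairs of regions are modelled jointly: a 4-dimensional random
effect (two intercepts, two slopes) with free covariance $\Psi$, a 2×2
within-occasion residual covariance $\Theta$ shared across occasions, and
the same covariates on intercepts and slopes (entry-age, entry-age² on the
intercepts, ICV, and sex). The quantity of interest is the slope-slope
correlation $\rho_{ss} = \Psi_{s_As_B}/\sqrt{\Psi_{s_As_A}\Psi_{s_Bs_B}}$.

Estimation is Bayesian because several regions have slope variances that
are tiny against the within-subject error, where ML routinely collapses
onto the boundary. Priors are the flat defaults of mainstream latent
growth software: $N(0, 10^{10})$ on fixed effects and the improper
inverse-Wishart $IW(0, -p-1)$ on covariances, equivalent to a uniform
prior on their elements. The improper prior is implemented literally — it
only shifts the posterior degrees of freedom — but if sampling
degenerates (non-positive-definite or non-finite covariance draws, the
known failure mode when variance components are near zero), the fit falls
back automatically to a weakly informative proper $IW(\epsilon I, p+1)$
and records `prior_fallback = TRUE` rather than failing silently.

The Gibbs sampler alternates conjugate blocks, with one deliberate design
choice: the fixed effects are drawn **collapsed**, from
$p(\beta \mid y, \Psi, \Theta)$ with the random effects integrated out,
followed by the per-subject random-effect draw. Random intercepts have SD
around 8% while residuals are near 1%, so the naive scheme that conditions
$\beta$ on the current random effects leaves the fixed intercepts nearly
confounded with the mean random intercept and mixes an order of magnitude
more slowly; the collapsed draw removes that funnel. Two or more chains
are run and split-chain potential scale reduction is reported per
parameter; fits above the threshold (default 1.05) are flagged, not
hidden. Posterior summaries report the median, the central 95% interval,
and the mass $m$ on the minority side of zero, classified as `*`
($m<0.05$), `**` ($m<0.005$), `***` ($m<0.0005$).

**Plausible values.** The retained draws of each subject's random slopes
propagate latent-variable uncertainty into secondary analyses. A subject
observed only at baseline contributes no slope information, and their
plausible-value spread correctly reverts to the population slope SD.

## Slope matrix and PCA

One slope estimate per person and region is formed as the mean of the
plausible-value means over every bivariate model containing the region
("mean of the means"). This estimator is deliberately simple and known to
attenuate correlations — single-number summaries discard the latent
uncertainty — but it retains the covariance pattern, which is what the PCA
consumes; the test suite checks that the sign pattern of its column
correlations agrees with the bivariate posterior medians for
well-separated pairs. Columns are then residualized on ICV, sex, and
entry-age (the literal covariate set of the adjustment step; entry-age²
is not included here), and the PCA eigendecomposes the **covariance**
matrix: the percent scaling already makes regions comparable, and regions
with larger slope variability should weigh more. Components are signed so
the largest-magnitude loading is positive, making output deterministic
under reordering, and are reported up to 85% cumulative variance by
default.

## The synthetic cohort generator

Raw data of this kind are not freely distributable, so the package ships a
generator that emulates the study design and is itself first-class, tested
code. Defaults, chosen once to mirror the design being emulated:

* **231 subjects**, entry-age from a truncated normal on [64, 87] with
  mean 70.8 and SD 5 (the published design gives the mean and range; SD 5
  reproduces a plausible spread within that range), 113/231 female.
* **ICV** normal with mean 1.45×10⁶ mm³, SD 1.4×10⁵ — typical adult
  values.
* **Waves** at 0, 1, 2, 4 years; follow-up times jittered with SD 0.1
  years (scheduling slip of a few weeks; the realized bin sets in such
  studies spread about this much), baseline exactly 0; 10% of subjects get
  an extra wave near 3 years, mirroring an extra follow-up offered to a
  subset.
* **Trajectories** generated directly on the percent scale from the
  random-slope model above — random slopes drawn jointly across regions
  under a specified correlation matrix — then multiplied back to mm³
  through each region's age-65 volume, so the scaling stage has real work
  to do.
* **Dropout** to 72% retention at the final wave: a per-wave logistic
  hazard on the standardized previous observed mean volume and on
  entry-age, monotone (once gone, gone), with the intercept calibrated by
  root finding so the expected retention hits the target. Missingness
  depends only on observed quantities, i.e. it is missing-at-random by
  construction, and a regression check in the suite confirms the
  never-observed wave value carries no information given the observed
  history.

What the generator does **not** emulate: scanner and segmentation
artifacts (the residual is homoscedastic Gaussian), site or cohort
effects, practice effects, non-linear trajectories, and informative
(MNAR) dropout. Passing tests on synthetic cohorts therefore demonstrate
that the estimation machinery recovers the truth under the model's own
assumptions — not that real data satisfy those assumptions.

## Numerical choices and problem sizes

* Optimizer retries across `nloptwrap`, `bobyqa`, `Nelder_Mead`; on
  noise-free degenerate data where mixed-model optimization is
  ill-posed, the fit falls back to pooled OLS with $G = 0$, the limiting
  ML solution.
* Ties in bin assignment go to the smaller bin value; ties in pairwise
  bootstrap comparisons split 0.5/0.5.
* The sampler default is 2 chains × 20,000 iterations (half burn-in),
  matching common practice for models of this size. The test suite uses
  2,000–3,000 iterations at n = 150–300 — enough for the collapsed
  sampler, whose worst-case split R-hat in those runs is ~1.07 — and 20
  univariate replicates, 10 bivariate seeds, 100 LRT replicates, and
  B = 200 bootstrap replicates; these sizes were chosen as the smallest
  that make the Monte-Carlo checks sharp.
* Wald 95% intervals on fixed effects by default; the bootstrap provides
  the intervals for the extrapolated losses.

## Known limitations

Linear person-specific trajectories only (a quadratic random slope is
deliberately out of scope; with four waves it is barely identifiable and
muddles interpretation); no autocorrelated or heteroscedastic residuals;
bivariate, not higher-order, joint models; the mean-of-means slope
estimator is biased toward attenuation by design; and the improper-prior
fallback, while documented in the fit object, changes the estimand
slightly for near-degenerate variance components.
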