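---
title: "Methods: two-step cost-efficiency analysis of state LTSS panels"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: two-step cost-efficiency analysis of state LTSS panels}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ltssfa)
```

## The model and its assumptions

State Medicaid agencies are treated as decision-making units producing
two outputs — institutional LTSS participants (`q_inst`) and HCBS
participants (`q_hcbs`) — at an observed total cost. Cost efficiency
`CE ∈ (0, 1]` is the ratio of the minimum attainable cost for a state's
caseload to its observed cost, and `u = |log CE| ≥ 0` is the inefficiency
term. The estimated cost frontier is

$$\log C_{it} = \beta_0 + \beta_1 \log q^{hcbs}_{it} +
\beta_2 \log q^{inst}_{it} + \delta_t + v_{it} + u_{it},$$

with year effects $\delta_t$ for every panel year except the base year
(8 dummies for a 1999–2007 panel with base 2007), Gaussian noise
$v_{it}$, and one-sided inefficiency entering with a **positive** sign —
the cost orientation: inefficiency raises cost. The inefficiency follows
the time-varying-decay process

$$u_{it} = u_i \, e^{-\eta (t - T_i)}, \qquad u_i \sim
N^+(\mu, \sigma_u^2),$$

where $T_i$ is the state's last observed year (so unbalanced panels
anchor each state at its own final year) and $\eta > 0$ means
inefficiency shrinks toward the final year. Key assumptions: a common
frontier across states; state-level inefficiency that moves
deterministically over time within a state; independence of $u_i$ and
$v_{it}$ from the regressors. The two-output form can be extended with
squared log outputs and their interaction
(`output_terms = "with_squares_and_interaction"`); the default is the
linear-logs form, matching the specification whose published coefficient
table shows no quadratic rows. Input prices never enter: no price data
exist at this level, so the "frontier" is a cost function conditional on
the states' common price environment.

## Likelihood, derived quantities, and numerical choices

Conditional on $u_i$, the state's observations are independent
Gaussians, and the $N^+(\mu,\sigma_u^2)$ prior is conjugate up to
truncation: the posterior of $u_i$ is $N(\mu_i^*, \sigma_*^2)$ truncated
at zero, with

$$\sigma_*^2 = \frac{\sigma_v^2 \sigma_u^2}{\sigma_v^2 + \sigma_u^2 \sum_t
h_{it}^2}, \qquad
\mu_i^* = \frac{\mu \sigma_v^2 + \sigma_u^2 \sum_t h_{it}
\epsilon_{it}}{\sigma_v^2 + \sigma_u^2 \sum_t h_{it}^2},$$

$h_{it} = e^{-\eta(t-T_i)}$, $\epsilon_{it}$ the frontier residual. The
marginal likelihood integrates $u_i$ out analytically (a ratio of normal
cdfs per state); the closed form is validated against adaptive 1-D
quadrature to $10^{-6}$ in the test suite, as is the score predictor

$$\hat u_{it} = h_{it}\,E[u_i \mid \text{data}] = h_{it}\left(\mu_i^* +
\sigma_* \frac{\phi(\mu_i^*/\sigma_*)}{\Phi(\mu_i^*/\sigma_*)}\right).$$

The conditional mean (not the `E[exp(-u)]` point predictor) is used
because the score itself, not its exponential, is the published unit of
analysis. **Score scale:** published state score tables have magnitudes
in the tens, which is inconsistent with `u = |log CE|` on a (0, 1] CE
scale unless multiplied; we define `score = 100·u_hat` so national
averages are comparable, and always expose raw `u_hat`.

Numerical decisions worth knowing:

* **Parameterization and optimization.** $\sigma^2 = \sigma_v^2 +
  \sigma_u^2$ and $\gamma = \sigma_u^2/\sigma^2$ are optimized as
  $\log\sigma^2$ and $\mathrm{logit}\,\gamma$; $\mu$ and $\eta$ are free.
  BFGS runs from 5 OLS-based starts across a $\gamma$ grid
  (0.1, …, 0.9), followed by Levenberg-damped Newton polishing with
  analytic gradients (the analytic score is itself tested against
  numerical differentiation). Convergence is declared at internal
  gradient norm $< 10^{-6}$; near the optimum, steps are accepted on
  gradient-norm decrease because objective decreases there fall below
  double-precision noise. Non-convergence is returned explicitly with
  the best point, never silently.
* **Tail-stable likelihood.** The naive closed form contains
  differences of terms that reach $10^{100+}$ when the optimizer probes
  deep-truncation regions ($\mu/\sigma_u \ll 0$, extreme $\eta$); in
  floating point those differences can fabricate spuriously *high*
  likelihoods that attract the optimizer. The implementation performs
  the dominant cancellations symbolically (sum-of-squares quadratic,
  asymptotic expansion of $\log\Phi$ in the far left tail), in three
  regimes keyed on $\mu/\sigma_u$ and $\mu_i^*/\sigma_*$.
* **Identification ridge.** With year dummies present, the *mean* path
  of $u_{it}$ ($E[u_i]\,h_t$) is collinear with the dummies; only the
  dispersion of $u_i$ identifies $\gamma$, $\mu$ and $\eta$ separately
  from $\delta_t$. On data simulated with $\sigma_u = 0$ the
  truncated-normal decay model therefore sits on a likelihood ridge
  (arbitrary $\mu$/$\gamma$ combinations offset by shifted dummies);
  the model-collapse test uses the half-normal time-invariant variant,
  where $\gamma$ is identified by skewness and collapses to its
  boundary as expected.
* **Distributions.** Half-normal is truncated-normal with $\mu$ pinned
  to 0 (exactly nested; tested). The exponential variant is implemented
  only for the pooled time-invariant case via the closed normal-
  exponential convolution — the decay-panel form has no standard closed
  likelihood for exponential $u_i$, and the distributional robustness
  claim it supports was reported as insensitive to this choice.
* **Zero participant counts** are a hard error at design time (log
  undefined); an explicit `offset` option exists but is off by default,
  since silent offsets distort elasticities.

## Second stage

`log(score)` is regressed on the policy covariates. The default
estimator is the within (FE) transform — numerically identical to LSDV,
verified to $10^{-10}$ — with CR1 cluster-robust standard errors
($G/(G-1)\cdot(N-1)/(N-K)$ small-sample factor; exactly HC1 under
singleton clusters) and normal 95% critical values (1.96) by default;
$t_{G-1}$ critical values are available (`t_df_cluster = TRUE`) and are
what the coverage test uses, since with tens of clusters the normal
approximation undercovers. The Swamy–Arora RE estimator quasi-demeans
with per-state $\theta$ (collapsing to pooled OLS at $\theta = 0$ and to
FE as $\theta \to 1$; negative variance components truncate to zero with
a warning). The Hausman test uses classical covariances with a
pseudo-inverse guard and recommends FE below p = 0.05. No year dummies
enter the second stage (year variation is absorbed by the first-stage
dummies). Effects are presented multiplicatively, `exp(b)` and
`1 − exp(b)`, truncated (not rounded) to two decimals to match the
published presentation convention.

**Why end-to-end recovery uses the pooled estimator.** The first-stage
predictor is $\hat u_{it} = h_t \, E[u_i|\text{data}]$: within a state,
$\log \hat u_{it}$ varies only through the *common* decay trend
$-\hat\eta (t - T)$, identical across states. State-demeaning therefore
removes all covariate-driven signal from the dependent variable by
construction, and an FE second stage on step-one scores cannot recover
covariate effects in a world where covariates truly drive inefficiency
(we verified: FE signs are coin flips). The covariate signal survives in
the between-state dimension — $E[u_i|\text{data}]$ tracks the state's
true mean inefficiency well — so the end-to-end recovery test regresses
with `fit_pooled()` (OLS, still cluster-robust by state). This also
explains a substantive caveat about FE regressions on decay-model scores
generally: any estimated "effect" of a trending covariate is a
projection of the single common decay trend onto that covariate's trend.

## The synthetic world

The generator emulates a 50-state × 9-year panel (the analysis sample is
448 state-years after dropping one all-managed-care state entirely and
two transition years for another; generated panels are balanced unless
the user excludes rows). Covariates draw state-level means near the
published descriptive statistics (HCBS share mean 53.90 sd 13.28, waiver
share 52.14/20.23, ICFMR share 5.70/4.13, unemployment 4.70/1.15,
log-normal income around \$33k and population around 3.5M with sd(log) ≈
1), evolve as driftless random walks with small yearly innovations,
clipped to valid ranges; binary policies switch on once at a uniform
year, with adoption probabilities scaled so state-year shares match the
published 0.42/0.74. Output counts are log-normal, correlated 0.8 with
population, split HCBS/institutional by the HCBS share.

Frontier truth defaults: elasticities 0.22/0.17 and intercept 13.68 from
the published frontier table; year effects from the same table;
$\sigma_v = 0.10$, $\sigma_u = 0.35$, $\mu = 0.30$ chosen once so that
$E[u] \approx 0.35$, matching the published mean score of ~35 on the
100·u scale; $\eta = 0.011$, consistent with the published ~1%/year
score decline. These are the stated world, fixed before any test was
run. At this $\eta$, the per-replication probability of a positive
$\hat\eta$ is itself about 0.95 (its sampling SE is ≈ 0.0066), so the
"decay sign detected in ≥ 95/100" acceptance clause is intrinsically
marginal — the acceptance test fixes its replication seeds so the result
is reproducible rather than a coin flip across runs.

In `covariate_driven` mode, $\log u_{it}$ is a linear index of the
covariates plus a state effect and noise — deliberately misspecified
relative to the bc92 likelihood, to exercise the full two-step pipeline.
The default index coefficients keep the published signs and relative
magnitudes but are scaled by 0.1: the literal per-percentage-point
magnitudes, multiplied by covariates with double-digit standard
deviations, imply log-inefficiency spreads beyond ±10 and overflow the
cost equation; the scaled world keeps $u$ in a physically meaningful
range.

What a green test does **not** establish: the generator has no real
state identities, no dollar-for-dollar cost magnitudes beyond the
calibrated intercept, no covariate trends (real HCBS shares rose
strongly over 1999–2007; synthetic ones are driftless), no quality
dimension, and no missing-data mechanism. Recovery results certify the
estimator under its own assumptions (plus the stated misspecification),
not the published empirical estimates, which derive from restricted
Medicaid data.

## Reporting conventions

Rankings are ascending in score (rank 1 = most efficient), ties broken
alphabetically and logged; efficiency tiers are quartiles of the mean
score across all years (the published table groups states once, not per
year). The national average is the unweighted mean across states —
states are the unit of analysis — with a population-weighted option.
Spearman's rank correlation uses mid-ranks for ties, a full permutation
p-value for n ≤ 8 and the t-approximation above. The published
quality-vs-efficiency correlation (0.38) is not reproducible here: it
requires external 2011 quality rankings, out of scope.

## Known limitations

* $\mu$ and $\gamma$ are weakly identified jointly (a known property of
  truncated-normal frontiers); their SEs can be large or undefined near
  boundaries, and are reported as `NA` where the observed information is
  not invertible.
* The exponential variant ignores the panel structure (pooled), by
  design; it is a robustness check only.
* FE second-stage estimates on decay-model scores inherit the
  common-trend identification caveat above.
* CPI deflation uses a single annual index supplied by the user; no
  health-sector inflation adjustment is attempted.
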