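---
title: "Methods: agreement estimation for digital-measure validation"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: agreement estimation for digital-measure validation}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(avtk)
```

## The problem

An analytical-validation (AV) study compares a novel digital measure (DM)
— a sensor-derived quantity summarised once per day — against a clinical
outcome assessment (COA) used as the reference measure (RM). Two
structural mismatches make this harder than a straight correlation:

* **Cadence.** The DM is daily; a multiday-recall RM is administered
  sparsely and asks about a span of days (the PHQ-9's two weeks). Data
  must be aligned to the RM's administration cadence and recall period
  before any agreement statistic is meaningful.
* **Measurement error.** Both sides are noisy indicators of latent
  constructs. The Pearson correlation between observed totals is
  attenuated below the correlation of the constructs; a latent-variable
  model is needed to estimate the construct-level relationship.

`avtk` implements the alignment rules, an estimator battery (Pearson r,
simple/multiple regression, two-factor CFA), fit evaluation, and a
simulator for validating the whole pipeline by parameter recovery.

## Data preparation

For each RM administration instance on date $t$ with recall period $d$
days, the recall window is $[t - d + 1,\, t]$, both ends inclusive — the
administration day itself counts as inside the window, which pins the
convention: a 14-day-recall instrument answered on Jan 14 has window
Jan 1–14. Among the observed DM days in the window, the `max_days = 7`
days closest to $t$ are selected; because the window ends at $t$,
"closest" is simply "most recent", and no ties are possible at daily
granularity. Seven days is the conventional span over which daily sensor
data yield reliable aggregates; it is configurable. Daily-recall RM data
are matched to exactly the selected DM days, with unobserved days kept as
missing (never imputed). Both series are aggregated to the administration
cadence as the arithmetic mean of observed values.

Item scores of an instance are summed and linearly mapped so the
instrument's minimum possible total is 0 and its maximum 100:
$(\mathrm{sum} - k\,\mathrm{min}) \cdot 100 / (k(\mathrm{max}-\mathrm{min}))$
for $k$ items. Partially answered instances carry no total: the original
methodology does not state how partial instances were scored, and scoring
them as missing is the conservative choice that avoids inventing a
prorating rule. Every administration instance per participant is retained
as a repeated record; the estimators treat records as independent, which
is a deliberate replication of the reference methodology rather than a
modelling recommendation (no mixed-effects adjustment is attempted, and
the report flags repeated measures only through its sample sizes).

Records with no DM data in the window are retained with missing means and
completeness flags, so study-level completeness metrics (fraction of
expected DM days observed, of fully answered instances, of window days
with daily-RM data) are computable from the same aligned table.

## Estimators

The Pearson correlation and regressions operate on the aggregated pairs
(DM window mean, scaled RM total), complete cases per model. The DM is
the regression response and RMs are predictors; predictor sets are each
RM alone, all multiday RMs, and all RMs plus the daily RM either as a
window mean or as individual day values. Adjusted
$R^2 = 1 - (1 - R^2)(n-1)/(n-p-1)$ can be negative; that is reported, not
clipped. Undefined correlations (constant input, fewer than 3 pairs) are
errors rather than silent zeros.

## The two-factor CFA

Indicators are the individual selected window-day DM values (factor 1)
and the RM item scores (factor 2). The methodology this implements uses
item-level RM information in the CFA but does not name the DM-side
indicators; individual window days are the only available repeated
DM measurements that satisfy the ≥3-indicators-per-factor identification
rule, and this choice is the package's own, stated here prominently.
Records with fewer than 3 observed DM days cannot support the day-level
factor and are excluded from the CFA (they remain in the correlation and
regression estimates, whose minimum is one observed day).

The model is simple-structure with correlated factors:
$\Sigma(\theta) = \Lambda \Phi \Lambda' + \Theta$, factor variances fixed
at 1 (so the single off-diagonal of $\Phi$ is the factor correlation
$\varphi$ itself), $\Theta$ diagonal. Estimation minimises the
normal-theory ML discrepancy
$F(\theta)=\ln|\Sigma|+\mathrm{tr}(S\Sigma^{-1})-\ln|S|-p$ on the
unbiased sample covariance $S$; the test statistic is
$\chi^2=(n-1)F_{\min}$ with $df = p(p+1)/2 - (2p+1)$. Likert items are
treated as continuous under ML; categorical estimators are out of scope.
Missing data are handled by listwise deletion by default (with the used
$n$ reported); a pairwise covariance is available behind a flag and is
rejected if indefinite.

Numerical choices: $\varphi$ is parameterised through $\tanh$ and
uniquenesses through $\psi = 10^{-6} + e^{u}$, giving an unconstrained
problem with analytic gradients; `stats::nlminb` runs from 5
deterministic starting points (moment-based loadings scaled by fixed
multipliers and damped starting correlations) with relative tolerance
$10^{-10}$ and at most 1000 iterations, keeping the best minimum. A
uniqueness ending at its floor is a Heywood case: flagged and floored
with a warning, never fatal, so batch analyses complete. Non-convergence
is likewise a reported flag. Loadings signs are normalised so each
factor's mean loading is positive, flipping $\varphi$ accordingly.

Fit indices use the independence baseline ($\Sigma_b=\mathrm{diag}(S)$,
$df_b=p(p-1)/2$, hence $\chi^2_b = -(n-1)\ln|R|$ for the sample
correlation matrix $R$):

* $\mathrm{CFI} = 1 - \max(\chi^2-df,0)/\max(\chi^2_b-df_b,\ \chi^2-df,\ 0)$
* $\mathrm{TLI} = (\chi^2_b/df_b - \chi^2/df)/(\chi^2_b/df_b - 1)$ (may
  exceed 1 for over-fitting models; values above 1 count as passing)
* $\mathrm{RMSEA} = \sqrt{\max(\chi^2-df,0)/(df\,(n-1))}$
* $\mathrm{SRMR}$: root mean square of correlation-scale residuals
  $(s_{ij}-\sigma_{ij})/\sqrt{s_{ii}s_{jj}}$ over the lower triangle
  including the diagonal.

Thresholds (CFI, TLI pass at ≥ 0.90; RMSEA, SRMR pass strictly below
0.08) are configurable; the overall verdict follows the majority of the
four, with a 2–2 split reported as "mixed". Correctness of the estimator
is checked three ways in the test suite: exact recovery of analytic
model-implied covariances ($\chi^2 = 0$, parameters to $10^{-6}$),
invariance of $\varphi$ and CFI/TLI/RMSEA to positive rescaling of any
indicator, and agreement within $10^{-3}$ with an independent established
SEM program (the `lava` package) on three committed covariance fixtures
whose oracle values were computed by that program and frozen alongside
the data.

## The simulator

`generate_study()` draws, per administration instance, a bivariate
standard-normal trait pair with correlation $\rho$ (`latent_corr`). The
trait expressed during a window is
$\eta' = \sqrt{1-\delta^2}\,\eta + \delta\,\zeta$ with one fresh $\zeta$
per window: $\delta$ (`temporal_drift`) models poor temporal coherence —
the construct moving between the days measured and the days recalled.
Each of the `dm_days_per_window` days measures $\eta'_1$ congenerically
with loading $\lambda_d$; each RM item discretises
$\lambda_r\eta_2 + \sqrt{1-\lambda_r^2}\,\varepsilon$ at the $L-1$
equal-probability normal quantiles (half-open bins); a one-item daily RM
measures $\eta'_2$ the same way. Missingness is independent per DM day,
RM item and daily-RM day. Windows of successive instances are consecutive
and non-overlapping, anchored at 2020-01-01.

Equal loadings within each side (parallel indicators) are the default so
closed-form Spearman–Brown reliabilities exist:
$\mathrm{rel}(m,\lambda) = m\lambda^2/(m\lambda^2 + 1 - \lambda^2)$, and
the population correlation between the DM window mean and a continuous RM
total would be $\rho\sqrt{\mathrm{rel}_1\mathrm{rel}_2}$
(`attenuated_r()`). Likert discretisation attenuates the observed value a
little further, so tests compare against this closed form with a band
that covers the discretisation gap, and the factor correlation — which
discretisation also biases slightly toward zero when ordinal items are
treated as continuous — is checked as a replicate mean against $\rho$
within ±0.03. Gaussian DM mode is used for all recovery work; count mode
(`round(exp(8 + 0.5z))`, floored at 0) produces step-count-like
magnitudes for realistic-looking data but would bias the closed forms
through rounding, so it is cosmetic.

Default study conditions (500 participants, one instance each, ρ = 0.5,
loadings 0.7, 9 items, 4 Likert levels, 14-day recall, 7 data days, no
missingness or drift) are the conditions under which the recovery
properties are asserted: 200 replicates for the attenuation study and 20
per point of the drift grid δ ∈ {0, 0.5, 0.9}, sizes at which replicate
means estimate the relevant expectations to well within the asserted
bands while the full suite stays quick. One master seed drives fixed
per-stage sub-streams (an LCG step of the seed plus a stage offset), so
each generation stage is reproducible in isolation.

What the generator does **not** emulate: informative (MNAR) missingness,
day-to-day autocorrelated DM noise beyond the single per-window drift
term, unequal item difficulties or loadings (accepted as parameters but
not defaulted), floor/ceiling effects common in symptom questionnaires,
and the idiosyncrasies of any real dataset. Passing recovery tests
therefore show the estimators are correct under the stated model — not
that real AV studies will exhibit these effect sizes.

## Known limitations

* Repeated instances are treated as independent records; standard errors
  and fit statistics ignore within-participant clustering.
* ML on Likert items is a pragmatic default; with few categories or
  skewed thresholds, categorical (e.g. polychoric) estimation would be
  preferable and is not provided.
* No FIML: missing data cost rows (listwise) or risk indefiniteness
  (pairwise).
* The CFA supports exactly the two-factor simple structure; it is not a
  general SEM language.
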