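---
title: "Composite platelet-reactivity scoring: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Composite platelet-reactivity scoring: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(plateletscore)
```

## The scoring model

The package's central construct is a rank-based composite of platelet
function readouts. For a variable measured on $n$ subjects, the van der
Waerden normal score of subject $i$ is

$$ s_i = \Phi^{-1}\!\left(\frac{r_i}{n+1}\right), $$

where $r_i$ is the mid-rank (ties share the average rank) and $\Phi^{-1}$
the standard-normal quantile. The $n+1$ denominator keeps every score
strictly inside $(\Phi^{-1}(1/(n+1)),\,\Phi^{-1}(n/(n+1)))$. Normal
scores are strictly monotone in the data and invariant under any strictly
increasing transform of it, so the composite never depends on the units
or skewness of the raw readouts.

A *cumulative score* is the **sum** of normal scores over a named
component set. Summation rather than averaging is deliberate: the spread
of the composite then grows roughly as $\sqrt{m}$ with the number of
components $m$, which matches how such composite scores are reported
(a seven-component global score spans roughly $\pm 2$ SD around group
means near $\mp 2$); `cumulate(aggregate = "mean")` is available for
users who prefer the scale-stable variant. The shipped component sets
are:

* `reactivity_aggregation` — A\(_\text{max}\) under arachidonic acid,
  collagen and ADP (whole-blood impedance aggregometry);
* `activation` — P-selectin and activated GPIIb/IIIa on circulating
  (resting) platelets;
* `p_selectin_expression`, `gpiibiiia_expression` — each antigen after
  AA and collagen stimulation;
* `reactivity_flow_cytometry` — the four stimulated antigen expressions;
* `global_reactivity` — the three A\(_\text{max}\) columns plus the four
  stimulated antigen expressions. This is the sum of the aggregation and
  flow-cytometry composites; treating the two antigens as the units of
  cumulation (each itself cumulated over its two agonists) gives the same
  vector.

The cumulative score is dichotomized at its own interpolated (type-7)
sample median; scores $\le$ Me take rank 0 ("lower reactivity") and
scores above it rank 1. The inclusive lower class means an odd cohort
with distinct scores splits $(n+1)/2$ versus $(n-1)/2$ — 126 versus 125
at $n = 251$. The integrative aggregometry indicator
$(A_\text{max}\times \mathrm{AUC})/1000$ is provided
(`integrative_indicator()`) and usable as a score component, but no
default set includes it: the downstream analyses are defined on
A\(_\text{max}\) and the antigen expressions.

## The synthetic cohort

Subject-level data of the motivating studies are not public, so the
generator emulates their statistical structure: a cohort of 251 subjects
aged 60–65 (125 women, 126 men), with per-sex marginal distributions
taken from published medians and IQRs and a sparse target matrix of
Spearman correlations.

**Marginals.** Each variable carries a distribution family and a per-sex
quartile triplet. Families: `normal` for analytes reported as mean ± SD
(RBC, P-LCR, uric acid, and other symmetric indices), `lognormal`
(optionally shifted) for right-skewed biochemistry, oxidative markers and
reactivity readouts, and `beta` scaled to known bounds for haematocrit
(0–100%) and age (60–65, configured as uniform). Parameters are
back-solved so the configured median and IQR are matched exactly for
normal ($\mu = \text{Me}$, $\sigma = \text{IQR}/1.349$) and
shifted-lognormal ($\sigma_{\log} = \operatorname{asinh}
(\text{IQR}/2\text{Me}')/0.6745$ with $\text{Me}'$ the shifted median),
and by moments for the scaled beta. Variables without published
summaries — thromboxane, TAS/TOS, the aggregometry AUCs, the LDL median
in women — carry synthetic defaults chosen once at physiologically
plausible values (e.g. AUC scaled at roughly ten times
A\(_\text{max}\), consistent with impedance-aggregometry traces over a
ten-minute window); they are marked as such here and never treated as
published values.

**Dependence.** Only pairwise rank correlations are reported for such
cohorts, so a Gaussian copula is the natural minimal model: target
Spearman correlations $\rho_S$ are mapped to the Pearson scale by
$r = 2\sin(\pi\rho_S/6)$ (exact for the Gaussian copula with continuous
margins), the multivariate normal is drawn under that matrix, and each
margin is transformed by its quantile function. Sparse targets combine
the reported reactivity–analyte associations (per-agonist PLT, PCT,
P-LCR, MPV, PDW, leukocyte, red-cell, age, uric-acid, lipid-peroxide and
thiol couplings) with conventional within-panel structure (PLT–PCT,
RBC–HGB–HCT, agonist-to-agonist coupling, and so on) that no study needs
to restate. Unspecified pairs default to zero; since a sparsely
specified matrix need not be positive definite, the Pearson matrix is
repaired by nearest-positive-definite projection (`Matrix::nearPD`,
Higham's algorithm — a better-conditioned implementation of the
eigenvalue-clipping idea) whenever needed. The shipped default does get
repaired; realized correlations for clipped pairs then deviate slightly
from their nominal targets, which is the honest consequence of jointly
infeasible pairwise targets.

**Sex.** Marginals are sex-specific and the copula couples variables
*conditional on sex*. This mirrors the reported associations, which are
sex-adjusted ("not adjusted for any confounding variables except of
sex"). A consequence worth knowing: in a mixed-sex draw, variables whose
locations shift with sex in the same direction acquire additional
marginal correlation from the mixture itself. Fidelity checks in the
test-suite therefore evaluate correlation targets on single-sex draws,
and `spearman_sex_adjusted()` (Fisher-z pooling over sex strata with
weights $n-3$) is the estimator matching the generator's semantics.

**Missingness** is MCAR, independently per eligible cell, capped at 3% —
the threshold above which the imputation policy refuses to act; sex and
age are never masked. No informative-missingness mechanism is modelled.

**What passing tests do and do not show.** The generator reproduces
marginals and pairwise rank structure; it does not emulate assay floor
and ceiling effects, batch drift, informative missingness, or any
higher-order dependence beyond the Gaussian copula. Pipeline behaviour
validated on these cohorts therefore demonstrates correctness of the
statistical machinery, not robustness to every artefact of real
laboratory data.

## Preprocessing

Outliers are *flagged, never silently dropped* (how flagged values were
handled upstream is generally unstated, so removal requires an explicit
decision by the analyst): Tukey fences at $1.5\times$IQR, or a two-sided
iterative Grubbs test at $\alpha = 0.05$ capped at two removals per
variable — both multipliers configurable. Grubbs on a constant vector is
a signalled error rather than an empty result, since its statistic is
undefined at zero variance.

Missing cells in variables under 3% missingness are imputed by the mean
of the $k = 5$ nearest complete donors (Euclidean distance on
standardized shared observed columns, normalized by the number of shared
columns); $k$ is configurable since no canonical value exists. Variables
at or above 3% are left untouched and reported — the cap is a policy
boundary, not a tuning parameter.

Group comparisons pass through an assumption gate: Shapiro–Wilk per
group and Brown–Forsythe (Levene on deviations from medians, via
`car::leveneTest`) across groups at $\alpha = 0.05$. On failure a
Box–Cox transform is attempted — $\lambda$ by profile maximum likelihood
on a $[-2, 2]$ grid of step $0.05$, with positivity shift $1 -
\min(x)$ when needed — and the assumptions are re-checked; the decision
(`parametric`, `transform-then-parametric`, `nonparametric`) routes the
test (Student's t or Mann–Whitney U). On truly normal homoscedastic
data the first-pass gate passes at about $0.95^3 \approx 0.86$, the
composite of three $\alpha$-level tests; this is verified by simulation
in the tests.

## Association and risk stages

`spearman_boosted()` returns the mid-rank Spearman coefficient with a
t-approximation p-value (exact permutation enumeration for $n \le 10$),
a seeded percentile-bootstrap CI (default $B = 2000$; the ANCOVA stage
uses $B = 10000$ by default, matching the heavier published convention
for adjusted comparisons), and leave-one-out jackknife diagnostics — the
"leave-one-out boosted" idea is implemented as stability reporting
around the estimate (min/max over deletions, influence flag on sign flip
or $|\Delta R_s| > 0.1$), not as a modification of the estimator, since
no definition of an LOO-modified Spearman estimator exists.

`ancova_boosted()` fits `dependent ~ group + covariates` and replaces
the F-test's normality assumptions with a permutation null: group labels
are permuted, both response and permuted indicator are residualized on
the covariates (Freedman–Lane style), and the p-value is the fraction of
$B$ resamples with $F^* \ge F_{obs}$, with the $+1$ correction that
keeps it strictly positive. Type-I error at the null is simulation-
checked to hold its nominal level.

`required_n()` implements the Fisher-z sample-size formula
$n = ((z_{1-\alpha/2} + z_{power})/\operatorname{atanh} r)^2 + 3$; at
$r = 0.22$, $\alpha = 0.01$, power $0.90$ it returns 300 after rounding
to tens — the design calculation behind a ~300-subject target cohort.

`or_2x2()` uses the Haldane–Anscombe $+0.5$ correction on zero cells and
Woolf log-scale CIs; `mh_pooled()` is the fixed-effects Mantel–Haenszel
estimator with the Robins–Breslow–Greenland variance. `build_forest()`
median-splits every predictor by the same $\le$ Me rule as the outcome
and pools the per-predictor tables — a construction mirrored from the
published forest figures. Because those "strata" are correlated
predictors measured on the same subjects, the pooled value violates the
independence premise of fixed-effects pooling; it is computed anyway for
comparability but labelled a *descriptive pooled OR* in the output
metadata. Logistic models report $\exp(\beta)$ with Wald CIs, a
likelihood-ratio $\chi^2$ for dropping each predictor (reported under
that explicit label, since published per-predictor $\chi^2$ values do
not name their generating test), and a Hosmer–Lemeshow test on $g = 10$
deciles of fitted risk (the conventional group count; duplicated
quantile edges are merged and the degrees of freedom adjusted).

## Multivariate stage

**Discriminant ranking.** Forward-stepwise selection on Wilks'
$\Lambda = \det(W)/\det(T)$; a variable's partial $\Lambda$ is the model
$\Lambda$ with the variable over the model $\Lambda$ without it, tested
by the Mahalanobis-distance F approximation with thresholds
F-to-enter $p < 0.05$ and F-to-remove $p > 0.10$. Lower partial
$\Lambda$ = larger unique contribution. Singular within-group covariance
triggers a small ridge ($10^{-6}$ of the total-scatter diagonal) with a
warning.

**Canonical analysis.** Canonical correlations come from
`stats::cancor` on standardized sets; structure loadings are
correlations between variables and their set's variates. Sequential
Bartlett $\chi^2$ tests give per-variate p-values; *extracted variance*
(mean squared loading, summed) and *total redundancy* (extracted
variance weighted by the paired variate's $\rho^2$) are reported over
the variates significant at 0.05 — a partial extraction, which is why
extracted variance is typically below 100%. "Best contributors" are
variables with $|$loading$| \ge 0.3$ on the first reported variate, a
stated convention rather than an inferential rule.

**Classifier panel.** Four judges predict the dichotomized class: kNN
(Chebyshev distance by default, $k$ chosen by leave-one-out error over
$\{3,5,7,9\}$), linear SVM at $C = 1$ (`e1071::svm`), Gaussian naive
Bayes (`e1071::naiveBayes`), and an adaptive-spline logistic classifier
written natively at minimal fidelity: forward selection of degree-1
hinge pairs at up to 7 interior quantile knots per feature, GCV backward
pruning (penalty 2 per basis beyond the intercept), then a binomial GLM
on the surviving bases, capped at 10 bases. The pruner never drops below
one hinge: a constant model evaluated leave-one-out under balanced
classes predicts the anti-majority and scores 0%, a degenerate judge of
no diagnostic value. Hyperparameters are unpublished for this kind of
panel, so all are configurable and logged in the result. Evaluation is
leave-one-out by default (in-sample on request, since published
accuracies may be either); consensus is per-subject majority with exact
ties counted as abstentions and scored incorrect, the tie rule recorded
in the output. For three independent judges of accuracy $p$, the
consensus closed form $p^3 + 3p^2(1-p)$ (78.4% at $p = 0.7$) is the
calibration check used in the tests.

## Numerical choices and degenerate inputs

* Ranks are mid-ranks everywhere; ties in a cumulative score are kept
  when the median is computed.
* A constant score vector dichotomizes to all-rank-0 with a warning (all
  values $\le$ Me); a constant vector is a signalled error for
  correlation and Grubbs.
* Empty 2×2 margins, all-zero MH cross-products, rank-deficient
  canonical sets and collinear ANCOVA covariates raise classed errors
  naming the problem rather than returning NaN.
* All resampling is seeded; derived stream seeds keep stages independent
  under one master seed, and every result object records its seed and
  iteration count.

## Problem sizes used in the checks

The test-suite validates distributional properties at sizes chosen to
make Monte-Carlo bounds sharp while keeping the suite quick to run:
marginal fidelity at $n = 50{,}000$ single-sex draws, correlation
fidelity at $n = 20{,}000$, parameter recovery and bootstrap coverage
over 1000 replicate cohorts of $n = 251$ (the study design size),
Hosmer–Lemeshow calibration over 1000 replicates of $n = 500$, and
permutation-ANCOVA type-I error over 2000 null replicates of $n = 100$
at $B = 2000$. The acceptance script reports mean recovered correlations
over 400 replicates per target.

## Known limitations

* The copula models pairwise monotone dependence only; tail dependence
  and nonlinear coupling are out of reach, and repaired (clipped) target
  matrices realize slightly different correlations than requested.
* Published classifier accuracies on the original cohort (e.g. 90.2%
  for Chebyshev kNN) are not reproducible without the raw data and are
  treated as narrative context, not targets.
* Single-pass kNN imputation only — no multiple imputation; flagged
  outliers are reported, not removed.
* The descriptive pooled OR should not be read as a meta-analytic
  summary, for the independence reason above.
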