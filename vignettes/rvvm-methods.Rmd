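---
title: "Measure-valued sample data: models, estimators and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measure-valued sample data: models, estimators and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rvvm)
```

## The measurement model

Classical sample data assume that measuring a unit $\omega$ produces a fixed
number. Many measurement processes do not: a bird bander may be 90% sure a
juvenile is female; a clinician may split their confidence between two
adjacent rating categories. `rvvm` represents such an observation as a
finitely supported probability measure $\mu_\omega$ over the possible values
of the target variable $Y$ — a *random-variable-valued measurement* (RVVM).
A *measurement protocol* $\rho$ assigns one such measure to every sampled
unit; a protocol whose measures are all point masses $\delta_{Y(\omega)}$ is
*trivial* and recovers classical data exactly, which is why bare numerals in
the CSV dialect are read as point masses: any classical dataset is a valid
RVVM dataset unchanged.

The information lost by a nontrivial measurement at a unit with true value
$y$ is the Kullback–Leibler divergence from $\mu_\omega$ to $\delta_y$, which
reduces to $-\log \mu_\omega(\{y\})$. We report it in natural logarithms
(nats); zero occurs exactly for a point mass on the truth, and a measure that
excludes the truth has infinite divergence and is reported as an error
rather than a number.

Because each record is a measure, the likelihood of a parameter $\theta$
becomes a *generalized likelihood*: the average of ordinary complete-data
likelihoods over all realizations ("completions") of the measure-valued
sample, weighted by the product measure of the per-unit measurements
(records are assumed mutually independent, and the sample a simple random
sample). Averaging commutes with Bayes' rule, so the generalized posterior
is the completion-weighted mixture of ordinary posteriors. Everything in
this package is an instance of that single fact.

## The Bernoulli case: `rvvm_binom()`

When $Y$ is Bernoulli, every admissible measurement is Ber$(\theta_\omega)$
with $\theta_\omega \in [0,1]$ (point masses are the endpoints). The
generalized likelihood depends on the data only through the total success
count $W$, whose distribution $\nu$ is the convolution of the per-unit
Bernoulli measures — the Poisson-binomial distribution. We compute $\nu$ by
iterative convolution (dynamic programming), which is exact to floating
precision and costs $O(n^2)$; at the desk scales this package targets
($n \le 10^4$) that is at most a few tens of milliseconds, and a
characteristic-function method would be the natural replacement beyond that.

Under a Beta$(\alpha,\beta)$ prior the generalized posterior is the
$\nu$-weighted mixture of Beta$(\alpha+k,\ \beta+n-k)$ densities,
$k = 0,\dots,n$. Its mean has the closed form
$$\hat\theta \;=\; \frac{\alpha + E_\nu(W)}{\alpha+\beta+n},$$
and its variance follows the law of total variance over $\nu$:
$$\operatorname{Var}(\theta \mid \rho(S)) \;=\;
  \frac{E_\nu\!\big[(\alpha+W)(\beta+n-W)\big]}{(\alpha+\beta+n)^2(\alpha+\beta+n+1)}
  \;+\; \frac{\operatorname{Var}_\nu(W)}{(\alpha+\beta+n)^2}.$$
We deliberately compute the variance through this decomposition, using the
exact first two moments of $\nu$, rather than through any expanded algebraic
form: the decomposition is unambiguous (the spread-of-component-means term
must carry the denominator $(\alpha+\beta+n)^2$, since the conditional mean
given $W=k$ is $(\alpha+k)/(\alpha+\beta+n)$), and the test suite checks it
against an independent route that sums the raw moments of the mixture
components, to $10^{-12}$, and against a two-stage Monte-Carlo sampler.

The default prior is the flat Beta(1, 1); the worked bird-banding example
uses Beta(15, 15) and states so explicitly wherever it appears. Credible
intervals invert the mixture CDF (a weighted sum of regularized incomplete
Beta functions) by bisection to $10^{-10}$ on the probability scale.

For all-point-mass data the mixture has a single component and everything
reduces exactly to the classical conjugate analysis — this classical
reduction is asserted exactly in the tests rather than assumed.

## Calibration: `calibration_report()`

A protocol is *calibrated* when for every measure it can emit, the measure's
expectation equals the conditional mean of the truth over the units that
received exactly that measure (the group $O_\omega$). Calibration is what
makes the generalized sample mean $\bar\rho(S)$ — the average of the
per-record expectations — an unbiased, consistent estimator of $E(Y)$, and
the Bayes estimate above asymptotically unbiased.

The empirical diagnostic partitions records by exact measure identity
(support and probabilities compared at full double precision; no fuzzy
merging of near-identical supports) and tabulates, per group, the measure
expectation, the empirical truth mean, their absolute discrepancy, and — for
binary measures — an exact two-sided binomial p-value, with Holm-adjusted
companions across groups. Exact grouping follows the definition; since real
assessors may emit confidences on an effectively continuous scale, an
optional `bin_width` pools Bernoulli confidences into bins, and output from
that pragmatic extension is flagged as binned. The package reports the
evidence but makes no accept/reject decision: no finite-sample threshold
for "calibrated enough" is hard-coded, because none is canonical.

## Regression: `rvvm_glm()`

For models beyond a single proportion, the generalized posterior is realized
literally as the mixture it is: every completion of the dataset (each
nontrivial cell replaced by a support value, weighted by the product of the
chosen atoms' probabilities) gets an ordinary Bayesian GLM fit, and the
pooled posterior concatenates draws — weight-proportionally in exact mode,
equally over sampled completions in Monte-Carlo mode. Pooling is *not*
moment-matching and deliberately not a missing-data combining rule: the
mixture is the posterior, so concatenation at the right proportions is the
correct operation, and it preserves features a combining rule would destroy
(e.g. the genuinely multimodal uncertainty about whether any juvenile male
was present in the bird example — a possibility that imputation from
observed complete cases can never entertain, since all definitively sexed
juveniles were female).

Exhaustive enumeration is capped at 4,096 completions; beyond that the fit
asks for Monte-Carlo mode, which draws `K` completions from the product
measure and pools their fits with equal weight (the draws are already
distributed per that measure, so their weights are not reused).

Each complete-data posterior is sampled by a self-contained adaptive
random-walk Metropolis sampler: proposals use a running empirical covariance
scaled toward a 0.234 acceptance rate during warmup, chains start from the
maximum-likelihood fit plus jitter, and split-$\hat R$ is computed per
completion, with fits above 1.05 flagged (never silently pooled). Defaults
are 4 chains × 2,500 kept draws after 2,500 warmup in exact mode, and
2 × 1,000/1,000 per completion in Monte-Carlo mode, where the pooled draw
count multiplies by `K`; the `control` argument swaps in other budgets, and
the sampler sits behind a single internal function so an external MCMC
backend can replace it without touching the pooling logic. Default priors
are weakly informative — Normal(0, 2.5) slopes, Normal(0, 10) intercept, and
a half-Normal(0, 10) residual scale for the linear family (the linear-scale
prior is our own weakly informative choice).

Measure-valued *covariates* are completed by exactly the same mechanism as
measure-valued responses. The single-proportion theory only needs responses;
the covariate case is a natural extension of the same mixture construction
and is exercised in the tests.

## The synthetic generators

`generate_birds()` emulates a songbird banding operation: 50 birds by
default, 76% adults, true female fractions 50% (adults) and 75%
(juveniles), two thirds of juveniles only partially sexed. Weights are
Normal by stratum — adult F/M 50/60 g, definitively sexed juvenile F/M
30/40 g, partially sexed juvenile F/M 20/30 g, all with sd 5 — so that
partial status confounds with weight; wing chord is Normal(11, 1) cm except
Normal(8, 1) for juvenile males, making sex recoverable from morphometrics
for juveniles only. The second parameter of every Normal is a **standard
deviation**, not a variance (the R convention). Partial status is an
independent Bernoulli(2/3) per juvenile, decided *before* the weight draw so
the stratified weight distributions apply; the mechanism that fixes which
birds are partial is our modelling choice, since only the counts are pinned
down externally.

The confidence a bander reports for a partial juvenile is drawn from a
discrete distribution on $\{0.1,\dots,0.9\}$ shaped like a Beta profile with
concentration 4 and exponentially tilted so its mean equals the stratum
female probability *exactly*; the bird's true sex is then drawn as
Bernoulli(confidence). Calibration therefore holds by construction, the
stratum female fractions are hit in expectation, and — because the support
is finite — the calibration groups $O_\omega$ are well populated, so the
empirical diagnostic can actually see the calibration at realistic sample
sizes. A continuous confidence distribution would be slightly more
naturalistic but would make every group a singleton; the discreteness is the
one place the generator departs from full realism, and it is the reason the
calibration test can use exact grouping rather than bins.

`generate_ratings()` emulates a 17-item clinician rating instrument: patient
latent severities are standard Normal, items perturb them (sd 0.5), the
perturbed value is cut into five categories with equal marginal mass, and
the reported confidence vector is a Dirichlet draw with concentration 10 on
the modal category plus a 0.5 base — infinite concentration collapses to the
classical single-category protocol. The fixed eight-patient first-item
encoding ships separately as `hamd_item1_example()` and is never touched by
the stochastic generator.

What passing tests on these generators show — and do not show — about real
data: they validate the estimators under *exact* calibration, independence
across records, and correctly specified strata. Real assessor confidences
are at best approximately calibrated, may be correlated within assessor or
session, and drift over time; none of that is modelled, and the calibration
diagnostic (not the generator) is the tool that speaks to it.

## Simulation studies and problem sizes

`run_wlln_study()` tracks the error of $\bar\rho(S)$ and of the Bayes
estimate over a grid of sample sizes (default 50/200/800, 200 replications
per cell), with an optional additive confidence shift that leaves truths
unchanged — the cleanest miscalibration, producing bias close to
shift × fraction-nontrivial. `run_consistency_study()` tracks the posterior
sd as the definitive subsample $m_1$ grows with the nontrivial subsample
$m_2$ tied to it (default grid 100/400/1600, 100 replications). These sizes
are the package's choices for a desk-scale study: they resolve the
$1/\sqrt{n}$ decay over a factor-16 range while keeping each study in the
low seconds. Monte-Carlo uncertainty is reported as a standard error per
cell; the tests use 3–4 standard-error margins.

One analytical point deserves honesty. With *independent* Bernoulli
measurements, $\operatorname{Var}_\nu(W) = \sum_i \theta_i(1-\theta_i) \le
n/4$ grows at most linearly, so both terms of the posterior variance above
vanish as $n \to \infty$ in *every* regime — including $m_2$ proportional to
$m_1$ with maximally uncertain Ber(0.5) measurements, where the posterior sd
still decays like $1/\sqrt{m_1}$ (and is in fact smaller than under the
$m_2 = \lceil\sqrt{m_1}\rceil$ rule, because a known-confidence record
contributes its expectation with no sampling noise). A genuine
non-vanishing floor would require $\operatorname{Var}_\nu(W)$ of order
$n^2$, which only dependent measurements can produce. The sense in which
partial information cannot be "sampled away" is therefore about *bias and
information* — an uncalibrated protocol's bias does not shrink with $n$, and
the per-record KL information loss is never recovered — not about the
posterior refusing to concentrate. The consistency study reports what the
mathematics gives; the corresponding acceptance test of a posterior-sd
plateau fails, and we have chosen to leave it failing rather than engineer a
dependent protocol it was not specified for.

## Numerical and degenerate-input choices

* Probabilities within $10^{-9}$ of summing to one are renormalized;
  anything further off is rejected — tolerant of decimal rounding in
  hand-entered files, strict against real errors.
* Zero-probability atoms are dropped at construction, so Ber(1) *is* the
  point mass at 1; support values compare exactly after canonical float
  parsing.
* An empty sample is legal in `rvvm_binom()` (the posterior is the prior)
  and rejected in the generalized mean (no classical analogue exists).
* A measure whose support leaves the declared range of $Y$, a truth outside
  its measure's support (unless flagged as measurement error), and a
  non-binary measure entering the Bernoulli machinery are all rejected
  rather than coerced.
* Grouping keys for calibration use full 17-digit representations, so two
  measures group together iff they are numerically identical.

## Known limitations

Only discrete, finitely supported measures are implemented; continuous
RVVMs and dependent (non-product) joint measurement measures are out of
scope, as is any modelling of classical measurement error beyond recording
the flag. The categorical generalization of the success-count machinery
(a multinomial $\nu$) is a straightforward extension that is deliberately
not included. Published regression tables for the bird example were produced
from a dataset whose generating seed is not public, so those fits are
checked by parameter recovery and qualitative ordering on matched synthetic
replicates, not digit-for-digit.
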