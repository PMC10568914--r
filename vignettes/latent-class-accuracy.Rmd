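---
title: "Estimating diagnostic accuracy without a gold standard: the latent class model behind blcda"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating diagnostic accuracy without a gold standard}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(blcda)
```

## The problem

Evaluating a diagnostic test normally means comparing it to a gold
standard. For Alzheimer's disease the gold standard is neuropathological
confirmation, unavailable in living patients; for mild cognitive impairment
no gold standard exists at all. Comparing cognitive screening instruments
(MoCA, MMSE, ADAS-cog) to an imperfect clinical reference biases their
estimated sensitivity and specificity in either direction.

Bayesian latent class models (BLCMs) sidestep the reference standard: true
disease status is treated as an unobserved binary class, and the
cross-classified results of K tests applied to the same subjects carry
enough information — once combined with informative priors — to estimate the
true prevalence and every test's accuracy jointly.

## The model

For K tests with results $t_k \in \{0, 1\}$ (1 = positive), prevalence
$\pi$, sensitivities $Se_k$ and specificities $Sp_k$, the probability of a
joint result pattern is a two-class mixture. Conditional on class, tests are
independent except for designated pairs, whose within-class dependence is an
additive covariance: for a dependent pair $(i, j)$ with within-class
positive-result margins $m_i, m_j$ and covariance $c$, the pair's joint cell
probabilities are

$$P(t_i, t_j) = m_i(t_i)\, m_j(t_j) + s(t_i, t_j)\, c,
\qquad s = \begin{cases} +1 & t_i = t_j \\ -1 & t_i \ne t_j \end{cases}$$

In the diseased class the margins are the sensitivities and the covariance
is $Cd$; in the non-diseased class the positive-result margins are
$1 - Sp_k$ and the covariance $Cn$ (equivalently the covariance of the
*negative* results with margins $Sp_k$ — covariance is invariant under
jointly complementing both results). Requiring all four pair cells to be
non-negative bounds the covariance by
`cov_bounds(p_i, p_j)`:
$\max(-p_i p_j, -(1-p_i)(1-p_j)) \le c \le \min(p_i(1-p_j), (1-p_i)p_j)$.

With one dependent pair and K = 3 (the packaged MoCA/MMSE/ADAS-cog panel,
MoCA and MMSE dependent because the two instruments measure overlapping
cognitive domains):

$$P(t_1,t_2,t_3) = \pi\,[a_1 a_2 + s\,Cd]\,a_3 + (1-\pi)\,[b_1 b_2 + s\,Cn]\,b_3$$

with $a_k(1) = Se_k$, $a_k(0) = 1 - Se_k$, $b_k(1) = 1 - Sp_k$,
$b_k(0) = Sp_k$. The observed data are the $2^K$ cell counts, with a
multinomial likelihood; the count-only multinomial coefficient is dropped as
constant in the parameters. Zero cells contribute zero to the
log-likelihood.

Priors are Beta for $\pi$ and each $Se_k$, $Sp_k$, and nominally
Uniform(−1, 1) for each covariance, truncated at evaluation time to the
admissible region above (values outside it would make cell probabilities
negative, so the effective prior is the truncation — exactly what a
rejection-based sampler does).

## Identifiability, and why the priors matter

A $2^K$ table has $2^K - 1$ degrees of freedom. For K = 3 with one
dependent pair the model has $1 + 2K + 2 = 9$ parameters against 7 degrees
of freedom: the model is *not identified by the data alone*. This is not a
defect of the implementation but a property of the design — one population,
three tests, within-class dependence. Informative priors supply the missing
information; this is standard practice in the BLCM literature and the reason
the packaged analyses come with carefully elicited Beta priors.

Two practical consequences:

* With flat priors, posterior means do not converge to the generating
  values however large the sample is; they settle on a prior-weighted point
  of the likelihood ridge. The package's recovery studies therefore use
  `weakly_informative_priors()`: every accuracy parameter gets the same
  Beta prior with mode 0.90 and 5th percentile 0.70 — "screening tests are
  informative, probably around 90% accurate, very likely above 70%" — and
  prevalence is Uniform(0, 1). This is the minimal soft identification; it
  favours no particular test.
* The likelihood has an exact mirror mode ($\pi \leftrightarrow 1 - \pi$,
  $Se \leftrightarrow 1 - Sp$). Informative priors make the mirror mode
  negligible, so the default sampler imposes no constraint. With weak
  symmetric priors a chain initialized in the mirror basin would report the
  reflected solution — a label-switching artifact — so `recovery_study()`
  (and `mcmc_config(constrain_youden = TRUE)`) restricts every test to
  $Se_k + Sp_k > 1$, the usual identifiability device.

## Prior elicitation

`elicit_beta()` converts a literature summary — a central value (mode or
mean) plus one pinned percentile — into Beta parameters, the convention
popularized by BetaBuster. The solver parameterizes the family by a
concentration $s$ (mode: $\alpha = 1 + ms$, $\beta = 1 + (1-m)s$) and finds
the concentration whose quantile matches the bound to $10^{-6}$. The
quantile need not be monotone in $s$ when the bound lies beyond the central
value on its own tail; the solver scans for all sign changes and returns the
most concentrated solution, erring loudly when no Beta satisfies the
constraints rather than silently fitting the nearest one.

The packaged prior fixtures store the published Beta parameters verbatim
(their original elicitation is not recoverable); their prevalence priors
have modes 0.108 and 0.080, matching the literature prevalences they encode.

## Posterior sampling

`sample_posterior()` runs a Metropolis-within-Gibbs sampler (compiled
core): one random-walk update per parameter per iteration, on the logit
scale for probabilities (with the Jacobian correction) and on the raw scale
for covariances, with the proposal width scaled to the current admissible
interval. Covariance proposals outside the admissible region are rejected
through the $-\infty$ log-posterior, realising the truncated Uniform prior.

Step sizes adapt toward an acceptance rate of 0.44 (the scalar random-walk
optimum) in batches of 50 iterations during burn-in — the burn-in doubles as
the adaptation phase — and are frozen afterwards, so the retained chain is a
valid fixed-kernel Markov chain. The default protocol is 100,000 iterations,
50,000 burn-in, thinning 10, one chain: 5,000 retained draws, which gives
effective sample sizes of 3,000–5,000 per parameter on the packaged tables.
Chains initialize from prior draws (covariances at 0), retrying up to 100
times if the starting density is degenerate; identical seeds give bitwise
identical chains. All randomness flows through R's RNG, so `set.seed()`
semantics apply end to end.

`diagnostics()` reports autocorrelations at chosen lags, effective sample
sizes (truncated autocorrelation sum, cut at the first non-positive lag),
per-chain trace summaries and — with two or more chains — the split-chain
scale-reduction factor. The `converged` flag requires ESS ≥ 400 per
parameter and scale reduction < 1.05 where computable; `run_blcm()` turns a
failed flag into a visible warning, never a silent pass.

## Summaries

`summarize_posterior()` pools chains and reports means, medians and
equal-tailed 95% credible intervals (2.5th/97.5th percentiles, type-7
quantiles). Equal-tailed intervals are used rather than HPD because that is
the conventional WinBUGS-style summary for these models. Youden's index is
computed from the posterior means, $J = Se_{mean} + Sp_{mean} - 1$, as the
published convention states; the draw-wise posterior of $Se + Sp - 1$ (whose
mean is identical) is also reported with its own interval.
`posterior_predictive_cells()` gives, per cell, the posterior mean expected
count and the fraction of draws whose expected count exceeds the observed
count; values near 0 or 1 flag cells the model cannot reproduce. Note that
the K = 3 *independence* latent class model is just-identified and can fit
most 8-cell tables exactly, so this check only has power against denied
dependence when the accuracy parameters are otherwise constrained.

## Cutoff selection for continuous scores

Dichotomizing a continuous score against a reference label uses the
empirical ROC: one candidate rule per midpoint between adjacent distinct
observed scores plus the two extreme rules, with the direction convention
made explicit (`lower` = low score is positive, as for MoCA/MMSE; `higher`
for ADAS-cog). `optimal_cutoff()` maximizes Youden's index; ties are broken
in favour of sensitivity (the screening context), then of the cutpoint
extending the positive region furthest. The midpoint cutpoint is canonical
and the rendered rule uses the smallest observed score strictly above it, so
integer MoCA-like scores with cutpoint 21.5 render as "< 22" and fractional
ADAS-like cutpoints such as 12.8 render as ">= 13".

## The synthetic-data generator

`simulate_panel()` draws the $2^K$ counts from one multinomial with the
model's cell probabilities; `simulate_subjects()` draws latent status,
within-class pair results from the explicit 2×2 joint (the same
margins-plus-covariance construction as the model, guaranteeing
generator/model agreement), independent results for the remaining tests, and
optional class-conditional normal scores. The default scenario
(`default_scenario()`) is a 20% prevalence population screened by three
tests with Se 0.87–0.92, Sp 0.90–0.92 and small positive within-class
covariances (0.03 diseased, 0.02 non-diseased) — accuracy and dependence in
the range reported for cognitive screening instruments.

What the generator deliberately does *not* emulate: covariate structure
(age, education), score distributions other than two-component normals,
longitudinal visits, and any form of verification bias. Passing recovery
tests therefore show the estimator is correct *under the model's own
assumptions*, not that real screening data satisfy them.

`recovery_study()` repeats simulate → fit → summarize across replicates and
reports per-parameter bias and 95%-interval coverage. The study sizes used
by the package's checks — 20 replicates at n = 20,000 under the default
protocol, with the weakly informative priors above — keep posterior-mean
bias below 0.03 for prevalence and accuracies and below 0.02 for the
covariances, with interval coverage at or near 1 (the informative-prior
directions yield conservative intervals).

## Numerical choices and edge cases

* Pattern order is fixed: descending binary with test 1 as the most
  significant bit, matching the row/column nesting of published 2×4
  three-test tables (outer test in rows, remaining pair in nested columns).
* Cell probabilities are clamped into [0, 1] only after verifying no cell
  is below $-10^{-12}$; a genuinely negative cell names the offending
  pattern and aborts.
* An all-zero count table is rejected before sampling.
* Elicitation failures (no Beta satisfies both constraints) are errors, not
  nearest fits; the solver tolerance is $|$quantile error$| < 10^{-6}$.
* Equal scores across all subjects yield only the two extreme ROC rules.
* `log_likelihood` returns $-\infty$ when a positive-count cell has zero
  probability; zero-count cells contribute exactly zero whatever their
  probability.

## Reproducing the published screening analysis

The packaged fixtures hold everything the published MoCA/MMSE/ADAS-cog
analysis needs: both count tables and both prior sets. Running the default
protocol on the AD table reproduces the published true prevalence of AD
(20.0%, 95% CI 17.6–22.6%) to the printed precision, and MoCA's accuracy to
~0.01. Some published posterior means cannot be reproduced from the
published inputs, however: marginal positivity rates
$\pi Se_k + (1-\pi)(1-Sp_k)$ are invariant to the dependence terms, and for
the MCI analysis the published means imply an ADAS-cog positivity rate of
0.34 where the published count table shows 464/1111 = 0.418. Any converged
fit of the published inputs must track the observed margins, so the
discrepancy lies between the published estimates and the published data, not
in the choice of dependence parameterization (an independent MCMC engine —
JAGS — fitted to the same inputs agrees with this package to three decimals
on every parameter; the package's test suite includes that cross-check).
The affected quantities are the MCI prevalence and the MCI ADAS-cog
accuracies, and to a smaller degree the AD specificities of MMSE and
ADAS-cog; the corresponding reproduction checks in the test suite document
the deviations rather than hiding them.

## Limitations

* One population per fit: the multi-population Hui-Walter design is out of
  scope.
* Dependence is pairwise and additive; higher-order or random-effects
  (latent trait) dependence is not modelled, and a test may belong to at
  most one dependent pair.
* No covariate adjustment of accuracies or cutoffs.
* The sampler is a random-walk scheme tuned for the small parameter blocks
  of screening panels (K up to ~6); it is not built for large K.
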