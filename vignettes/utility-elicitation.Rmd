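---
title: "Eliciting utilities of life satisfaction and aggregating them into Representative Life Satisfaction"
author: "lsutility"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Eliciting utilities of life satisfaction}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(lsutility)
```

## The elicitation model

`lsutility` analyses standard-gamble choices over six ordinal well-being
states `F < E < D < C < B < A`, where `F` is death and the living states are
anchored by descriptive vignettes rated on the 0–10 life-satisfaction scale.
A gamble offers a certain baseline state against a lottery between a better
and a worse state; at the indifference loss probability `p` the expected
utilities balance:

$$U_b = p\,U_l + (1-p)\,U_w.$$

Because respondents cannot report `p` directly, each gamble walks a
descending ladder of loss probabilities (1/2, 1/5, 1/10, 1/100, then powers
of ten down to one in a million). Rejection moves down the ladder; the first
acceptance ends it. The indifference point is the *geometric* midpoint of
the bracketing odds, `p = sqrt(p_acc_max * p_rej_min)`, because the grid is
(roughly) geometric: an arithmetic midpoint would be dominated by the upper
bracket for small probabilities. Two boundary conventions follow from the
ladder itself: rejecting even the one-in-a-million loss is coded as `p = 0`
("infinite aversion"), and accepting the very first step gives
`p = sqrt(0.5)` — the most risk-tolerant value the instrument can express.
Both conventions have visible consequences downstream: every elicited
loss-aversion value of a noise-free decider lies on the lattice
`{0.414, 2.162, 6.071, 30.62, 315.2, ...}` of midpoint odds, which is an
instrument artifact to keep in mind when reading medians and quartiles.

Chaining the four adjacent-state gambles upward from the anchors
`U_F = 0, U_E = 1` solves the curve state by state
(`U_w = (U_b - p U_l)/(1-p)`). Estimation uses the `E` anchor rather than
`A` so that heavy risk aversion — which compresses the top of the curve —
does not push all utilities against the anchor where rounding would make
them indistinguishable; `rescale_to_reporting()` converts to the
`U_F = 0, U_A = 1` reporting scale afterwards. A `p = 0` step makes the next
state's utility exactly equal to the baseline's, and because each subsequent
increment is proportional to the previous one, flatness then propagates
exactly up the remainder of the chain. This is the correct algebraic
consequence of the model, not a numerical artifact.

Dropping the death gamble leaves three equations over the living states with
anchors `U_E = 0, U_A = 1`. These are coupled rather than sequential;
`living_utilities()` solves the 3-unknown linear system in closed form. The
no-death curve matters for two reasons: some respondents show infinite
aversion to any death risk, which flattens the living portion of the full
chain to a point, and the national life-satisfaction distribution covers
living states only.

## Aversion measures

Substituting the indifference relation into the loss/gain ratio gives
`lambda = (1-p)/p`; `lambda = 1` is risk neutrality. The bounded transform
`lambda' = (lambda-1)/(lambda+1)` is symmetric about zero — `lambda` and
`1/lambda` map to opposite equal magnitudes — and is the scale on which the
package averages within participant and correlates across participants.
Summaries follow a drop-then-pool rule: a participant missing (undecidable)
any gamble in a subset is dropped from that subset's pooled row, while still
contributing to every gamble they did decide. Infinite aversion enters
pooled means as `lambda' = 1` and proportion statistics as `lambda > 1`;
only analyses needing a finite curve exclude it. Quartiles use the
median-unbiased rule (`stats::quantile(type = 8)`, configurable): the
convention is not dictated by the model, and with lattice-valued data the
choice is mostly invisible anyway.

## The discrete-choice model

The chained solve is exactly identified — four gambles, four unknowns — so
it quantifies no error. Four additional non-adjacent personal gambles
overidentify the personal curve, and `fit_participant()` estimates, per
participant, a binomial logit

$$P(\text{choose gamble}) =
  \frac{e^{\sigma U_{\text{gamble}}}}{e^{\sigma U_{\text{gamble}}} +
        e^{\sigma U_{\text{baseline}}}}$$

over every accepted/rejected ladder step of the eight personal gambles
(each step treated as an independent Bernoulli observation — the natural
reading of fitting "the set of gambles", with a caveat that within-ladder
dependence is ignored). Free parameters are the choice sensitivity `sigma`
and the utilities of `D, C, B, A`; the anchors stay fixed. Choices of note:

* **Unconstrained utilities.** No monotonicity constraint is imposed during
  optimisation; violations are flagged (`monotone = FALSE`) rather than
  hidden, since a non-monotone MLE is informative about data quality.
* **Multi-start.** The optimiser (L-BFGS-B) starts from the participant's
  chained curve when finite and always from the risk-neutral linear curve;
  the better likelihood wins, so added starts can only improve the fit.
* **Bounds and tolerances.** `sigma` is bounded to `[1e-6, 1e6]` and
  optimised on the log scale; the likelihood convergence tolerance is 1e-8.
  All-accept or all-reject data leave `sigma` unidentified: the fit returns
  `converged = FALSE` with `sigma` at its bound instead of raising.
* **Tie rule.** In percent-correctly-predicted, a predicted probability of
  exactly 0.5 counts as incorrect — deterministic and conservative.

Fit quality is summarised by McFadden's pseudo-r² against the coin-flip
null. On the reporting scale the choice-model curves track the chained ones
with visibly less between-participant spread, which the test suite asserts
as a variance inequality over a simulated cohort.

## CPT probability weighting

The sensitivity analysis replaces probabilities with the linear-in-log-odds
weighting `w(p) = delta * p^gamma / (delta * p^gamma + (1-p)^gamma)`, whose
log-odds are affine in the log-odds of `p` (slope `gamma`, intercept
`log delta`). With the certain baseline as reference point and identity
value functions, the weighted indifference relation is equivalent to the
unweighted one at the effective probability
`p* = w(p) / (w(p) + w(1-p))`. Two presets cover a median and an extreme
small-probability overweighter (`0.77/0.44` and `1.19/0.27`); both
parameters are extrapolations below `p = 0.01`, where weighting has not
been measured empirically, so the module estimates nothing — it only maps
presets or user values through the pipeline. By default the weighting is
applied to the indifference probability itself (the minimal consistent
reading); an endpoint-wise mode that reweights the bracketing grid odds
before taking the midpoint is available behind the `mode` argument for
sensitivity. Identity parameters reproduce the unweighted pipeline
bit-for-bit, which the tests assert, and overweighting of small losses
shrinks every interior aversion measure towards neutrality.

## Representative Life Satisfaction

Each participant's living-state curve is placed on the 0–10 scale at the
cohort's mean vignette ratings (near 2, 4, 6, 8, 10) and linearly
interpolated; below the lowest knot the lowest segment's slope is extended
(clamped nonnegative), above the highest knot the function is constant. The
national distribution enters as four bins (0–4, 5–6, 7–8, 9–10) with
configurable within-bin representative values defaulting to midpoints
(2, 5.5, 7.5, 9.5) — the source releases state no within-bin value, so the
midpoint is the neutral choice, and a sensitivity sweep over representatives
is a one-argument change. The distribution mean reported beside RLS is
computed from the same representatives, so mean-vs-RLS differences are
internally consistent (an externally quoted mean of the unbinned data will
differ slightly).

RLS is the constant life-satisfaction level equivalent to the distribution
under the cohort's utilities:

* **mean_utility** — after dividing each curve by its share-weighted SD
  under the reference distribution (equal "voting power"; SD-only, since any
  centring cancels in the equation below), solve
  `mean_i fn_i(c) = mean_i E_dist[fn_i]` by bisection. Flat curves have no
  defined scale and are excluded.
* **median_participant** — the median of each participant's own certainty
  equivalent `CE_i = fn_i^{-1}(E_dist[fn_i])`: the lowest level that half
  the cohort would consider at least as good as the distribution. This is
  the default reading of a "median curves" summary because it delivers that
  quantile statement literally; a pointwise **median_curve** variant is
  retained as the alternative reading.

`median_participant` needs no normalisation: each `CE_i` is invariant to a
positive affine transform of that participant's utilities. It is *not*
invariant to arbitrary increasing transforms — expected utility is cardinal,
so `E[g(f(X))] != g(E[f(X)])` for non-affine `g` — and the test suite
asserts exactly the affine class. Jensen's inequality guarantees
`RLS <= mean` whenever all curves are concave, with equality only in the
linear case; both bounds are asserted on simulated cohorts. Certainty
equivalents invert curves by bisection to 1e-9 on the life-satisfaction
scale, returning the lowest attaining value on flat stretches and clamping
(with a flag) outside the range.

## The synthetic cohort

`simulate_cohort()` stands in for survey data so that every stage is
testable against ground truth. Each agent has a geometric-decrement utility
curve built from a target loss aversion (`utilities_from_lambda()`), so all
its adjacent gambles share one true `lambda` and a true indifference point
`1/(1+lambda)`; a logistic choice sensitivity; a societal-context multiplier
on the loss term; an extra multiplier on societal death gambles; a per-step
can't-choose rate; and optional CPT weighting (identity parameters reproduce
the expected-utility agent exactly). Defaults emulate a 300-respondent UK
survey: personal `lambda'` drawn from a truncated normal with mean 0.33 and
SD 0.34; societal multiplier lognormal around 2.3 (the ratio of pooled
societal to personal median aversion); death multiplier lognormal around 5
(societal death gambles show roughly five-fold stronger aversion than
living-state societal gambles, while personal gambles show no death
premium); sensitivity lognormal around 3; a 1% can't-choose rate; vignette
ratings centred on (10, 8, 6, 4, 2) with a 5.1% order-violation rate; and
party shares matching the recruitment quotas. All randomness flows through
per-agent substreams derived from one master seed, so an agent's record does
not change when the cohort grows.

What the generator does *not* emulate: within-ladder consistency (stochastic
agents redraw independently at each step, so mildly incoherent sequences
occur, as in real data, but there is no revision behaviour); learning or
fatigue across the twelve gambles; any dependence of aversion on
demographics or politics (the political scale is generated independently of
`lambda`, mirroring the absence of such a correlation); and response-time or
attention-check behaviour beyond a flag. Passing parameter-recovery tests
therefore shows the pipeline inverts its own data-generating process
correctly — not that real respondents satisfy the model.

## Validation statistics

`cronbach_alpha()` implements the classical item-covariance form (the
sample/population variance convention cancels in the ratio);
`mann_whitney()` wraps the rank-sum test with `U` oriented to the first
sample, exact enumeration when the smaller group has at most 8 untied
observations and the tie-corrected normal approximation otherwise;
`pearson_r()` is the product-moment correlation with the `t`-based p-value.
`mde_correlation()` inverts the t test: the smallest `|r|` that reaches
significance at the given sample size, i.e. the critical value — the
50%-power convention, which is what "would in principle be significant"
means; an explicit 80%-power variant is provided and clearly larger.
`mde_median_lambda()` finds, by bisection over simulated location shifts at
a stated dispersion, the smallest median difference the Mann-Whitney test
detects with the requested power; it is stochastic and seed-controlled, and
is a documented stand-in since no closed form exists for the median/U-test
pairing.

## Problem sizes and numerical conventions

The test suite simulates cohorts of 10–200 respondents for structural and
property checks and one 300-respondent end-to-end run; discrete-choice
recovery uses 200 replicated ladder sets (~3,000 observations) per agent.
These sizes make the full suite run in about a minute while leaving
simulation error well inside the asserted tolerances. Key numeric
conventions in one place: tie at exact indifference is accepted (this fixes
the risk-neutral reference behaviour and makes the lattice exact); chained
residuals are exact to 1e-12; bisections run to 1e-9; `sigma` bounds
`[1e-6, 1e6]`; quantile type 8; probabilities are stored in files as exact
fraction strings and parsed once.

## Limitations

The elicitation grid quantises aversion onto the midpoint lattice, so
fine-grained individual differences below grid resolution are invisible by
design. The chained solve propagates any early-step error upward
(overidentification via the choice model is the partial remedy). RLS is
doubly nonlinear — scale to utility, utility back to scale — and therefore
sensitive to the low-satisfaction bin and to the within-bin representative
choice; for comparing policy alternatives, averaged normalised utility is
better conditioned than RLS itself. States worse than death are out of
scope, and the CPT analysis is a sensitivity test built on extrapolated
weighting parameters, not an estimate of them.
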