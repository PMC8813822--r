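---
title: "Estimating temporal-discounting contagion with grid-Bayesian posteriors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Estimating temporal-discounting contagion with grid-Bayesian posteriors}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tdcontagion)
```

## The task and the model

`tdcontagion` simulates and analyses a five-block delay-discounting task
in which a participant alternates between choosing for themselves (Self1,
Self2, Self3) and choosing on behalf of two simulated agents (Other1,
Other2). Every trial offers a smaller-sooner amount (£1–20, immediate)
against a larger-later amount (delayed by 1, 7, 14, 28, 42, 60 or 90
days). Preferences follow the hyperbolic discounting model

$$V = \frac{M}{1 + kD},$$

where $M$ is the amount, $D$ the delay in days and $k$ the discount
rate, combined with a softmax (logistic) choice rule

$$P_{LL} = \frac{1}{1 + e^{-\beta (V_{LL} - V_{SS})}}$$

with inverse temperature $\beta$. Both parameters are treated on the
base-10 log scale: $\log k \in [-4, 0]$ (near-total delay insensitivity
to very steep discounting) and $\log \beta \in [-1, 1]$ (noisy to
near-deterministic choice). All internal computation uses
$k = 10^{\log k}$, $\beta = 10^{\log \beta}$; the base-10 convention is
the standard one for discount rates in this literature.

## Trial-wise grid inference

Parameters are estimated by exact Bayesian updating on a discrete grid
(default $101 \times 51$ evenly spaced nodes, i.e. log k quantised below
0.05; resolution is a configuration knob). The prior is uniform; each
trial multiplies in the likelihood of the observed choice at every node
and renormalises. Because the posterior is a normalised product of
likelihoods, sequential updating is identical to a single batch update
and invariant to trial order — both properties are tested to tight
numerical tolerance.

The block schedule follows the task's social-learning logic:

* **Self1** starts from a uniform prior, with $\beta$ free.
* **Other1** inherits the end-of-Self1 posterior — one's own preferences
  seed learning about another person — with $\beta$ clamped to 1
  (the agents are defined to act with $\beta = 1$, so the $\log \beta$
  axis is inert and the log k marginal tracks beliefs about the agent).
* **Self2** and **Self3** restart from a uniform prior so that the
  strong posteriors formed about the agents do not leak into Self
  estimation; **Other2** inherits the end-of-Self2 posterior.

The canonical point estimate of a participant's $\log k$ is the marginal
posterior mean (the MAP and variances are also reported). The original
analysis environment did not state its online point estimator; the mean
is smoother on a discrete grid and is used everywhere an online estimate
is needed, with the MAP exposed for comparison.

The value 0.3 used as the initial $\log \beta$ point estimate in Self
blocks is interpreted as the starting value for the adaptive
pair-generation heuristic before any data arrive, not as a non-uniform
prior: the prior is explicitly uniform, and a point value cannot
parameterise a distribution over the grid.

## Adaptive choice pairs

With only 30–50 trials per block, randomly drawn pairs waste most trials
on foregone conclusions. The generator draws integer amounts uniformly
(larger-later strictly larger) and delays uniformly from the menu, then
keeps candidates whose predicted $P_{LL}$ under the current running
estimate lies within 0.4 of the indifference point, falling back to the
least extreme candidate if 40 draws fail. At least half of every
generated set satisfies the informativeness band at any plausible
$\log k$; in practice nearly all pairs do. The exact pair-construction
procedure used with human participants is not public, so this generator
is a documented stand-in designed for parameter recovery, not a
reconstruction.

## Agents, feedback and accuracy

Each agent's $\log k$ is the participant's Self1 posterior mean $\pm 1$,
clipped into $[-4, 0]$, with presentation order counterbalanced. The
$+1$ agent is *impulsive* (steeper discounting), the $-1$ agent
*patient*. When clipping collapses an agent onto the participant's own
value the direction is *degenerate* and the record is flagged rather
than scored. Agent choices are sampled from the $\beta = 1$ softmax
rather than taken as the higher-probability option; feedback compares
the participant's choice to that sampled choice. A consequence worth
stating plainly: even a learner that knows the agent's parameters
exactly cannot exceed $E[p^2 + (1-p)^2]$ accuracy, and with pairs
concentrated near the indifference point the synthetic cohorts sit in
the high-50s to low-60s percent range. Empirical accuracies in
comparable human experiments are higher (mid-70s to mid-80s), which
suggests human responders behave closer to argmax than to
probability-matching; the sampled-choice convention was chosen because
the agents themselves are defined generatively through choice
probabilities, and it is recorded here as a known gap between the
simulator and real data.

## The contagion statistic

Contagion — the drift of one's own preferences toward those of an
observed other — is quantified per agent as a signed Kullback–Leibler
divergence between the Self-block posteriors bracketing that agent's
block (Self1/Self2 around Other1, Self2/Self3 around Other2):

$$D_{KL}^{\pm} = s \cdot \sum_i p_i \ln \frac{p_i}{q_i},$$

where $q$ and $p$ are the pre- and post-exposure log k marginals and
$s = +1$ when the posterior-mean $\log k$ moved toward the agent, $-1$
when it moved away, $0$ for no movement. Choices made here where the
source material is silent, all exposed as options:

* **Direction of the divergence:** $D_{KL}(\text{post} \,\|\, \text{pre})$ —
  the new belief relative to the old.
* **Marginal, not joint:** the divergence is computed on the log k
  marginal; $\log \beta$ is a nuisance dimension (and is inert in Other
  blocks anyway). A joint-grid divergence would mix decision-noise
  drift into a preference-shift measure.
* **Units:** natural log (nats); bits are a flag.
* **Zero mass:** $q$ nodes are floored at $10^{-30}$ and renormalised
  before the log ratio, keeping the divergence finite on truncated
  grids; $p$-zeros contribute nothing.
* **"Normalisation":** the signing rule above is the only
  normalisation applied; no additional rescaling.

Exclusion rules mirror the published procedure: participants whose mean
signed divergence falls outside a 3-SD cohort fence are removed, and a
participant whose two agents share a direction (possible near the log k
boundaries) keeps only the agent at the greater distance from their own
discount rate. Every decision is logged.

For ingested trial logs the agent parameters are not part of the CSV
schema. They are re-derived by fitting each Other block's recorded
`agent_choice` column from a uniform prior with $\beta = 1$ and snapping
to the nearer of Self1-mean $\pm 1$: the agent's own choices identify
its log k essentially perfectly, whereas the participant's gradual
tracking of the agent does not. Simulated-cohort analyses may instead
pass the ground-truth agent table, as the original task script — which
constructed the agents — effectively did.

## The synthetic cohort generator

No human data accompany the analysis, so the generator is the test bed,
and its defaults are the study conditions rather than tuning knobs:

* Population $\log k \sim N(-1.68, 0.67)$ for NT and $N(-2.28, 0.78)$
  for ASC cohorts, truncated to $[-4, 0]$; $\log \beta \sim N(-0.19,
  0.35)$ / $N(-0.08, 0.52)$ truncated to $[-1, 1]$ — the observed group
  statistics.
* 30 or 50 trials per block; agent order alternates across participants.
* AQ subscale totals (Likert scoring, five subscales of ten items
  scored 1–4) are drawn from normals with the observed group means and
  SDs, rounded and clipped to $[10, 40]$. Item-level simulation is out
  of scope.
* Ages and genders follow the observed sample demographics (used only
  by the control-matching step).

The generative contagion mechanism is a convex shift applied after each
Other block:

$$\log k \leftarrow \log k + \alpha_{\text{dir}} \, (\log k_{\text{agent}} - \log k),$$

with $\alpha \in [0, 1]$ per direction. $\alpha = 0$ yields a null
cohort (the divergence measure must then be mean-zero), $\alpha = 1$
snaps the participant onto the agent. This is a stand-in law — the
measurement target is the shift, and no generative mechanism for human
contagion is established — chosen as the simplest monotone
interpolation. Defaults are $\alpha_{\text{patient}} = 0.4$,
$\alpha_{\text{impulsive}} = 0.25$: a modest shift with the
patient-direction bias reported in the contagion literature, fixed once
and not revisited. During Other blocks the synthetic participant learns
the agent with the same grid learner the analysis uses (the
well-specified case) and responds by sampling the $\beta = 1$ softmax
at its current posterior-mean estimate of the agent.

What passing tests on these cohorts do show: the estimator recovers
known parameters (r ≥ 0.9, MAE ≤ 0.3 at 50 trials), the signed
divergence is null-calibrated at $\alpha = 0$, detects $\alpha = 0.5$
shifts decisively, and increases monotonically in $\alpha$. What they
do not show: anything about response processes real participants use
(lapses, side biases, argmax-like responding, non-stationary
$\beta$), item-level questionnaire structure, or dropout.

## The statistical battery

* **One-sample contagion tests** are gated by Shapiro–Wilk at
  $p < 0.05$: normal data go to a one-sample t-test, non-normal to the
  Wilcoxon signed-rank test. Cohen's d (mean/SD) is always reported.
* **Yuen's trimmed-mean t-tests** (independent with Welch-style
  fractional df, and paired) use a default trim of 0.2 — the
  robust-statistics convention, as the original analyses did not state
  a trim. At trim 0 the independent variant reduces exactly to Welch's
  t-test (tested to $10^{-8}$). The effect size is the explanatory
  measure $\xi$: the square root of the ratio of the variance of the
  group trimmed means (as fitted values) to the Winsorized variance of
  the pooled data rescaled by its normal-consistency constant
  ($1 - 2\gamma - 2c\,\phi(c) + 2\gamma c^2$ with $c = \Phi^{-1}(1-\gamma)$,
  $\approx 0.4121$ at $\gamma = 0.2$), capped at 1.
* **Bayes factors** for t-designs are default JZS: a Cauchy(0, 0.707)
  prior on the standardised effect size, integrated numerically against
  the noncentral-t likelihood. Where the frequentist branch is a
  Wilcoxon test, the BF is computed on the t-equivalent and labelled an
  approximation; regression and correlation BFs use the BIC
  approximation, likewise labelled. Rank-based Bayes factor samplers
  are out of scope.
* **Equivalence testing**: the bound is the $|d|$ at which a two-sided
  two-sample t-test attains a target power (default 33%), obtained by
  exact inversion of the noncentral-t power function — at
  $n = 12$/group this gives $d = 0.649$. The interval-null Bayes
  factor compares posterior to prior odds of $\delta \in [-d, d]$ under
  the same Cauchy prior, with the tail mass computed as total minus
  interior because a near-empty tail defeats relative-tolerance
  quadrature.
* **Control matching** selects one control per case: exact gender,
  direction-compatibility (a case with two same-direction agents is
  never matched to a control with two agents in the opposite
  direction), nearest age, seeded random tie-breaks, no reuse.
* All tests are two-sided at $\alpha = 0.05$ with no multiplicity
  correction, matching the published analysis style. Type-I error of
  the battery is verified by simulation to lie in $[0.03, 0.07]$.

## Numerical and degenerate-input choices

Likelihoods are computed with the saturating logistic; nodes may reach
exactly 0 or 1 in double precision, which per-trial renormalisation
tolerates (an all-zero posterior raises a degeneracy error rather than
propagating NaN). Ties in subjective value resolve through the softmax
itself ($P = 0.5$); there is no deterministic tie-break. Zero-variance
inputs to the t-family tests raise degenerate-data errors rather than
returning 0/0. Truncated-normal population draws use rejection
sampling, with $\sigma = 0$ treated as the degenerate point draw.
The noncentral-t density's limited-tail-precision warning is silenced
inside the Bayes-factor quadratures; the quadrature tolerances are far
coarser than the affected digits.

## Problem sizes

Validation uses 200-participant cohorts at 30 trials per block for the
null-calibration, detection and monotonicity checks (the
common-random-numbers seed is shared across contagion strengths), 200
participants at 50 trials for parameter recovery, and 2000 replicates
for type-I calibration; these sizes give binomial/Monte-Carlo standard
errors comfortably inside the asserted bounds. The acceptance script
uses 100-participant cohorts, chosen as the package's own standard
demonstration size.

## Known limitations

* The pair generator and the contagion law are stand-ins; both are
  documented as such above.
* Synthetic accuracy undershoots human accuracy (see the agents
  section) — conclusions about accuracy *levels* should not be read off
  the simulator, though direction contrasts and correlations are
  well-defined within it.
* The grid imposes hard parameter bounds; posteriors for participants
  near $\log k = -4$ or $0$ are truncated, which the degenerate-agent
  flag and greatest-distance rule absorb downstream.
* Other-block inference assumes the participant knows $\beta = 1$; a
  misspecified-learner robustness option (a "lazy" softmax on a decayed
  estimate) is a natural extension and is not implemented.
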