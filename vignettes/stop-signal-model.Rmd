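---
title: "An ideal-observer account of stop-signal response times"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{An ideal-observer account of stop-signal response times}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette is the package's account of the model it implements, the
choices made where the design was genuinely open, and the limits of what
the synthetic-data experiments can show.

## The decision problem

Each trial of the stop-signal task is modeled as a partially observed
stopping problem in discrete time (default: `D = 50` steps of 22 ms,
matching an 1100 ms deadline). Two hidden variables matter: the go-stimulus
identity `d ∈ {0, 1}` and the trial's stop status `s ∈ {0, 1}`; on a stop
trial the signal switches on at a geometric onset step θ with hazard `q`
(mean SSD `1/q` steps). Two conditionally independent Bernoulli channels
deliver one bit-like observation each per step: the go channel at rate
`q_d` vs `1 − q_d` depending on `d`, the stop channel at rate `q_s` before
onset vs `1 − q_s` after. Channel informativeness is the distance of these
rates from one half; the defaults `q_d = 0.55` (a hard discrimination) and
`q_s = 0.72` make stop evidence much stronger than go evidence, which is
what makes late stopping possible at all.

### The exact filter

The belief state that drives behavior is `(p_d, p_s)` — the posterior on
`d = 1` and on `s = 1`. `p_s` alone is not Markov: the stop-channel
likelihood differs before and after onset, so the filter carries the exact
sufficient statistic `(w0, w1, w2)` = P(go trial), P(stop trial, signal
pending), P(stop trial, signal on), and reports `p_s = w1 + w2`. Each step
applies the onset transition (mass `q·w1` flows to `w2`), then Bernoulli
likelihood weighting and renormalization; `p_d` updates independently from
the go channel. The test suite checks this filter against brute-force
enumeration over `(d, s, θ)` and verifies the martingale property of both
posteriors under the one-step predictive distribution.

### The optimal policy

Costs are normalized to the go-error cost: `c = 0.002` per step of delay
and `c_s = 0.4` per stop error (a stop error is deliberately cheaper than
a go error, which is why responding under uncertainty can be rational).
The Bellman recursion over the belief state runs backwards from the
deadline, where the value is explicit (`c·D + 1 − p_s`). The default
discretization is the 200 × 200 grid over `(p_d, p_s)` with nearest-bin
(containing-bin) lookup and no interpolation; for belief transitions
inside the backup, the scalar `p_s` is split into pre-/post-onset
components using the prior onset dynamics `P(on | stop, t) = 1 − (1−q)^t`.
Action ties resolve to Wait (act only when strictly cheaper); on Go the
response is the currently more probable identity, with an exact tie at
`p_d = 0.5` broken by a fair coin.

A config-selectable *exact* mode instead discretizes the full
`(p_d, w1, w2)` sufficient statistic (simplex cells whose midpoint sums
exceed one are unused). Two numerical points about it:

* The last two value layers are available in closed form (`V^D`
  explicitly; `V^{D−1}` as the minimum of the Go cost and the terminal
  expectation, using the martingale of `p_s`), so the exact mode's backup
  at `t = D − 2` evaluates successor beliefs exactly rather than snapping
  them to cells. Not discretizing what is explicit is strictly better
  numerics and is what lets the small-deadline policy match brute-force
  policy enumeration to machine precision.
* Near knife-edge parameters the cell-midpoint action is genuinely
  ambiguous. With `q_d = 0.55` and 20 bins, the reachable posterior
  `p_d = 0.55` after one observation lies exactly on a bin edge *and*
  exactly at the boundary where one more sample stops having
  discrimination value; whichever cell receives it, the midpoint sits on
  the wrong side for one of the two tie-break conventions. The
  equivalence tests therefore use parameters in general position
  (`q_d = 0.57`, `0.62`), where the optimum is isolated.

## Learning across trials

P(stop) follows a dynamic belief model: the stop-trial rate persists with
probability `α = 0.75` per trial (an assumed change about every four
trials) or is redrawn from Beta(2.5, 7.5), whose mean 0.25 matches the
session's stop frequency; the posterior lives on 100 equal-width midpoint
bins, where quantization error (≤ 0.01 on the predictive mean) is far
below the effects of interest. The session starts from the generic prior,
and block boundaries do *not* reset the model (a reset flag exists): the
task statistics do not change at block boundaries, so a rational learner
has nothing to reset for — only the block-initial exclusion (below)
acknowledges the analyst's ignorance of initial beliefs.

E[SSD] follows a scalar Kalman filter in seconds (`Q = 0.03`, `R = 0.15`,
prior `N(0.35, 1)`). On go trials the filter diffuses without a correction
step, so the influence of past SSDs fades with intervening go trials. Each
trial's *prior* means parameterize the within-trial model: `r = P(stop)`
and `q = 1/E[SSD in steps]`, the latter clipped into `[1/D, 1]` to keep
the geometric onset proper (a nonpositive prior mean — possible since the
filter is Gaussian — is clipped to one step and counted on the record's
`clipped_essd` attribute).

## The synthetic sessions

`generate_session()` reproduces the experimental design: 12 blocks × 75
trials, stop trials iid with probability 0.25 (an exact-count-per-block
option exists), SSD uniform on {100, …, 600} ms, fair go identities,
1100 ms deadline, and the point scheme (50 points per error, 3 per 100 ms
of delay). `simulate_observer()` closes the loop trial by trial. Policies
are cached on a lattice of 14 P(stop) values (0.10–0.75 by 0.05) × 11
E[SSD] values (8–18 steps) and looked up by nearest lattice point;
recomputing a 200 × 200 × 50 dynamic program per trial would be wasteful,
and the simulated RT surface is smooth in both coordinates. Cohort-level
heterogeneity (per-subject jitter on `α`, `Q`, `R`, `c`, `c_s`) is
available but off by default: the reference experiments use a homogeneous
cohort at the parameters above.

What the generator does *not* emulate: perceptual nonstationarity and
learning of the channel rates, non-decision time, lapses, motor noise,
fatigue, and any reward sensitivity beyond the fixed cost structure.
Passing tests on synthetic cohorts therefore demonstrate the internal
consistency of inference, policy and analysis — not that human data would
yield the same parameter estimates.

## The analysis pipeline

Analyses operate on trial logs (tibbles) and exclude, per block, the
leading run of go trials before the first stop trial (on average three
trials at a 25% stop rate, none at all a quarter of the time), because
initial beliefs are unconstrained by evidence. Predictors are attached by
running both learners forward over the experienced sequence — strictly
prior quantities, verified by permutation-of-the-future tests. The
pattern table averages RT (and model P(stop)) over the 8 three-trial
stop/go histories preceding each correct go trial, requiring consecutive
trial numbers so that excluded rows invalidate spanning patterns. The
model-free SSD predictor (mean of the last two SSDs, eligibility limited
to go trials directly following a stop with at most three go trials
between the two stops) is kept separate from the Kalman predictor.

Group-level regressions use equal-count binning (populations differ by at
most one; default 10 bins) with OLS on the bin means, and the variance
partition discretizes both predictors into 5 equal-count bins, averages RT
per nonempty cell, and compares the P(stop)-only to the two-predictor OLS
fit on the same cell means (nesting bounds the share at one).

**Fitting the learning parameters is different from displaying them.** The
grid searches (`fit_dbm_alpha()`, `fit_kf_params()`) default to the
*unbinned* R² — equivalently, equal-count bins of size one. With wide
bins, the bin means of any smooth candidate predictor are almost
noise-free, so the binned R² saturates near its ceiling and what varies
is dominated by the candidate's range, which systematically favors the
smoothest (most persistent, smallest-gain) candidate over the generating
one. The per-trial objective is the consistent member of the same family;
in the package's recovery experiments it identifies the Kalman ratio `R/Q`
cleanly, while coarse binning does not. Coarse binning remains available
via `n_bins` for comparability with the group displays.

## Known limitations

* **Residual persistence bias.** The policy-cache lattice quantizes the
  RT-generating P(stop) into 0.05-wide levels. A candidate persistence
  slightly above the generating value correlates a little better with the
  quantized series than the generating value itself, so recovered `α`
  tends to land a grid step or two above a generating 0.75 at the
  20-subject scale; on the suite's fixture cohort the recovered value is
  0.85, just outside one grid step of the truth.
* **Stop-error speed.** Empirically, stop-error responses are faster than
  correct go responses. Under the default parameterization the model's go
  RTs (roughly 850–1000 ms) lie almost entirely above the 100–600 ms SSD
  range, so the censoring mechanism that produces fast stop errors barely
  operates; most simulated stop errors are late responses that override an
  already-detected signal, and the closed-loop difference between
  stop-error and correct-go RT is near zero (its sign varies with the
  seed). Reproducing the classical effect would need a faster-responding
  regime (stronger go evidence or a higher delay cost) than the default
  parameter set.
* **Pattern-table tails.** The SSS history occurs on only ~1.5% of trials,
  so its pooled RT mean at 20 subjects carries a standard error of several
  milliseconds; orderings among the rare patterns are unstable even though
  the frequency/recency trend is robust.

## Problem sizes

The test suite and the acceptance script use: 2,000 simulated go trials
per condition for the RT sweeps (14 P(stop) conditions at E[SSD] = 10;
11 E[SSD] conditions at P(stop) = 0.45); 2,000 stop trials per SSD for
the inhibition function; one 20-subject closed-loop cohort of 900 trials
each for recovery, variance partitioning and pattern analyses; deadlines
of 3–4 steps with a 20-bin exact-mode grid for the brute-force optimality
comparison. These sizes give condition-mean standard errors of a few
milliseconds while keeping a full run to a couple of minutes on one CPU.
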