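# stopsignal

Rational-observer modeling of response-time variability in the stop-signal
task (SST). In the SST a subject discriminates a go stimulus on every trial
(left/right, within an 1100 ms deadline) but must withhold the response
when an infrequent stop signal sounds some 100–600 ms after go onset (the
stop-signal delay, SSD). Trial-to-trial go RT in this task is usually
treated as noise; this package implements a model in which much of that
variability is the rational consequence of the subject continuously
re-estimating two environmental statistics — how often stop trials occur,
P(stop), and when the stop signal tends to arrive, E[SSD] — and re-tuning
an optimal response strategy accordingly. It is aimed at computational
cognitive scientists who want to simulate the model, attach its
trial-by-trial predictors to trial logs, and run the associated
RT-variability analyses.

## The model

**Within a trial** the observer sees two independent Bernoulli evidence
streams in discrete time steps: `x^t` about the go identity `d ∈ {0,1}`
(rates `q_d` vs `1−q_d`) and `y^t` about the stop signal (rate `q_s`
before onset, `1−q_s` after). On a stop trial the onset step θ is
geometric with hazard `q`, so E[SSD] = 1/q steps. Exact Bayes filtering
yields the belief state `b^t = (p_d^t, p_s^t)` — the posterior
probabilities of `d = 1` and of this being a stop trial (internally the
stop side is the exact three-component sufficient statistic, split by
whether the signal is on yet). Costs are normalized to the go-error cost:
`c` per step of delay and `c_s` per stop error. The Q-factors

    Q_go(b^t)   = c·t + c_s·p_s + (1 − p_s)·min(p_d, 1 − p_d)
    Q_wait(b^t) = E[ V^{t+1}(b^{t+1}) | b^t ]          (t + 1 < D)
    V^D(b^D)    = c·D + (1 − p_s)

define the optimal Go/Wait policy by backward induction over a 200 × 200
belief grid (`compute_policy()`); the RT is the step at which the policy
first says Go. The policy has two Go regions (confident identity, low
stop belief) around a central Wait region.

**Across trials**, P(stop) is tracked by a dynamic belief model
(`dbm_run()`): the stop-trial rate γ persists with probability α = 0.75
per trial or is redrawn from Beta(2.5, 7.5); the predictive mean is the
next trial's P(stop). E[SSD] is tracked by a scalar Kalman filter
(`kf_run()`; Q = 0.03, R = 0.15 s², prior N(0.35, 1)) that diffuses on go
trials and assimilates the observed SSD on stop trials. The two prior
estimates parameterize the next trial's within-trial model (`r = P(stop)`,
`q = 1/E[SSD]`), closing the loop (`simulate_observer()`,
`simulate_cohort()`). The model predicts mean go RT increasing
approximately linearly in both P(stop) and E[SSD].

The analysis side (`attach_model_predictors()`, `pattern_rts()`,
`binned_linear_regression()`, `variance_partition()`, `fit_dbm_alpha()`,
`fit_kf_params()`) reproduces the standard pipeline: sequential-effect
tables over three-trial histories, equal-count binned RT regressions on
the model predictors, partitioning of binned RT variance between them, and
grid-search recovery of the learning parameters.

## Worked example

```r
library(stopsignal)
set.seed(1)

gen <- gen_params(q_d = 0.55, q_s = 0.72, q = 1/10, r = 0.25, D = 50)
pol <- compute_policy(gen, cost_params(c = 0.002, c_s = 0.4))
pol
#> Optimal stopping policy (pair mode), D = 50 steps
#>   grid 200 x 200 over (p_d, p_s); r = 0.25, E[SSD] = 10.00 steps
#>   Go fraction of the grid at t = 1: 2.6%

trials <- simulate_trials(pol, d = rbinom(5000, 1, 0.5), s = FALSE)
mean(trials$rt_ms[trials$outcome == "go_correct"])
#> [1] 809.7471
table(trials$outcome)
#> discrim_error    go_correct      omission
#>          1171          3819            10
```

With weak go evidence (`q_d = 0.55`, roughly the hard coherence
condition), a 25% stop-trial prior and an expected SSD of 10 steps
(220 ms), correct go responses average ~810 ms against the 1100 ms
deadline, with frequent discrimination errors and almost no omissions —
the deliberately slow, cautious regime the cost structure induces.

A small closed-loop cohort, with the sequential-effect table over
three-trial stop/go histories (most recent trial last; RT in ms):

```r
cohort <- simulate_cohort(n_subjects = 2, config = session_config(n_blocks = 4),
                          cache = policy_cache(grid = c(100, 100)), seed = 7)
pattern_rts(exclude_block_initial_go_runs(cohort))
#>   pattern   n mean_rt se_rt mean_pstop se_pstop
#> 1     GGG 154     844  12.7      0.216 0.000883
#> 2     SGG  47     821  26.0      0.245 0.001674
#> 3     GSG  45     841  25.1      0.259 0.001615
#> 4     GGS  47     851  21.7      0.276 0.001510
#> 5     SSG  13     897  30.3      0.283 0.002589
#> 6     SGS  20     854  36.0      0.304 0.002213
#> 7     GSS  11     884  37.5      0.322 0.005974
#> 8     SSS   2     924  44.0      0.343 0.000401
```

Model P(stop) rises strictly with the frequency and recency of stop trials
in the recent history, and mean go RT follows the same trend (noisily, at
this small cohort size): the signature sequential effect.

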