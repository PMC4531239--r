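# shared, lazily built fixtures; the policy cache is reused across test
# files so each (P(stop), E[SSD]) policy is computed once per test run
.fixtures <- new.env(parent = emptyenv())

shared_cache <- function() {
  if (is.null(.fixtures$cache)) .fixtures$cache <- policy_cache()
  .fixtures$cache
}

# the study-condition cohort: 20 subjects, 12 blocks x 75 trials, 25% stop
# trials, paper learning/cost parameters, fixed seed
shared_cohort <- function() {
  if (is.null(.fixtures$cohort)) {
    .fixtures$cohort <- simulate_cohort(n_subjects = 20, cache = shared_cache(),
                                        seed = 1)
  }
  .fixtures$cohort
}
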