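# Shared fixtures: the calibrated baseline and small seeded random draws.

bp <- function(...) {
  p <- baseline_params()
  if (...length() > 0) p <- modify_params(p, ...)
  p
}

# A deterministic stream of random valid games for property loops.
random_games <- function(n, seed = 20260922) {
  set.seed(seed)
  lapply(seq_len(n), function(i) {
    telemedgame::sample_parameters(sampling_spec())
  })
}

random_states <- function(n, seed = 4711) {
  set.seed(seed)
  lapply(seq_len(n), function(i) runif(4, 0.02, 0.98))
}
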