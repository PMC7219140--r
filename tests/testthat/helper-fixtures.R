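# Shared fixtures, built in code. Heavier objects are cached per test run.

fixture_env <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (is.null(fixture_env[[key]])) fixture_env[[key]] <- force(expr)
  fixture_env[[key]]
}

# A short model-A realisation reused across tests.
sim_a_short <- function() cached("sim_a_short", simulate_gc_benchmark("A", n = 800, seed = 42))

# A fast linear-oracle configuration (few trials, small surrogate count).
linear_cfg <- function(n_trials = 2, seed = 7, ...) {
  gc_config("linear_gc_oracle", n_trials = n_trials, seed = seed,
            detection = detection_spec(n_permutations = 39), ...)
}

# Tiny LSTM windows for engine-level checks.
random_windows <- function(C = 2, T_len = 6, B = 4, seed = 99) {
  withr_seed <- function() {
    set.seed(seed)
    list(X = array(rnorm(C * T_len * B), dim = c(C, T_len, B)), y = rnorm(B))
  }
  withr_seed()
}
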