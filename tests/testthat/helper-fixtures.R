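# Shared fixtures: everything is generated in code at test time.

BJ_DIRS <- c(15, 75, 135, 195, 255, 315)

# small random trial set (independent Poisson counts, not model-generated)
random_trials <- function(n_neurons = 3, per_neuron = 6, T_ = 480L,
                          rate_per_bin = 0.06, p_release = 0.5,
                          seed = 1) {
  set.seed(seed)
  trials <- list()
  for (n in seq_len(n_neurons)) for (i in seq_len(per_neuron)) {
    tb <- if (stats::runif(1) < p_release) 420L else NA_integer_
    trials[[length(trials) + 1L]] <-
      new_trial(paste0("n", n), stats::rpois(T_, rate_per_bin), 1L, 331L,
                sample(BJ_DIRS, 1), sample(BJ_DIRS, 1), tb)
  }
  trial_dataset(trials, neuron_ids = paste0("n", seq_len(n_neurons)))
}

# tiny simulated population without spike history (fast engine paths)
tiny_truth <- function(N = 4, rank = 1, seed = 1, template = "mixed") {
  sample_ground_truth(template, N = N, rank = rank, seed = seed,
                      schedule = task_schedule(touch_bar = "none"))
}

expect_rel_equal <- function(a, b, tol = 1e-8) {
  expect_lt(max(abs(a - b)) / max(1, max(abs(b))), tol)
}
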