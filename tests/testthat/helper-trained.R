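# Trained networks are expensive; cache them across test files (helpers are
# sourced once per test run). Epoch budgets are the suite's problem sizes
# (see the methods vignette): large enough for the self-organization to
# express itself, small enough to keep a multi-seed replication fast.
BAR_EPOCHS <- 150     # asymmetric bar runs (map coverage needs the longer run)
SYM_EPOCHS <- 60      # symmetric-control bar runs
RDS_EPOCHS_NF1 <- 8
RDS_EPOCHS_NF2 <- 8
NOISE_TRIAL_EPOCHS <- 120

.trained_cache <- new.env(parent = emptyenv())

trained_bar <- function(seed, rule_mode = "asymmetric",
                        epochs = BAR_EPOCHS) {
  key <- paste("bar", rule_mode, seed, epochs)
  if (is.null(.trained_cache[[key]])) {
    .trained_cache[[key]] <- run_bar_training(
      seed = seed, epochs = epochs, rule = learning_rule(rule_mode))
  }
  .trained_cache[[key]]
}

# response of every neuron to every probe (max settled activity per frame)
bar_responses <- function(network, probes = bar_training_set()) {
  vapply(probes, function(s)
    apply(present_sequence(network, s)$activity[[1]], 2, max),
    numeric(network$fields[[1]]$params$dim^2))
}

# peak-response population: neurons within 5% of the stimulus's best response
peak_population <- function(resp_col, frac = 0.95) {
  which(resp_col >= frac * max(resp_col))
}
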