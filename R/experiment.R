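#' Simulation-3 protocol: decoding translational flow
#'
#' Runs the full random-dot decoding pipeline: build 25 seeded dot
#' configurations, translate each in the 4 cardinal directions (5 frames,
#' toroidal wrap) and split 80/20 by configuration; train NF1 (afferents
#' fixed at 1) then NF2 with the asymmetric Hebbian rule; train the
#' perceptron readout on NF2 responses of the training split; report argmax
#' classification accuracy on both splits.
#'
#' @param seed master seed (stimuli, weight init, presentation order and
#'   decoder shuffles all derive from it).
#' @param epochs_nf1,epochs_nf2 epoch caps for the two fields; `NULL` uses
#'   the preset caps (200 each). Saturation stopping applies either way.
#' @param perceptron_epochs delta-rule epochs.
#' @param alpha perceptron learning rate.
#' @return a list with `train_accuracy`, `test_accuracy`, `network`,
#'   `decoder`, `reports` and the stimulus splits.
#' @export
run_rds_decoding <- function(seed = 1, epochs_nf1 = NULL, epochs_nf2 = NULL,
                             perceptron_epochs = 300, alpha = 0.1) {
  sets <- rds_training_sets(seed = seed * 1000)
  preset <- load_preset("rds_translate")
  net <- new_network(preset, seed = seed)
  fit1 <- train_layer(net, 1, sets$train, epochs = epochs_nf1,
                      seed = seed + 11)
  fit2 <- train_layer(fit1$network, 2, sets$train, epochs = epochs_nf2,
                      seed = seed + 23)
  net <- fit2$network
  labs <- function(ss) vapply(ss, function(s) as.numeric(s$direction_deg),
                              numeric(1))
  ftr <- nf_features(net, sets$train)
  fte <- nf_features(net, sets$test)
  dec <- new_perceptron(ncol(ftr), classes = c(0, 90, 180, 270),
                        alpha = alpha)
  dec <- train_perceptron(dec, ftr, labs(sets$train),
                          epochs = perceptron_epochs, seed = seed + 37)
  list(train_accuracy = decode_accuracy(dec, ftr, labs(sets$train)),
       test_accuracy = decode_accuracy(dec, fte, labs(sets$test)),
       network = net, decoder = dec,
       reports = list(nf1 = fit1$report, nf2 = fit2$report),
       train_set = sets$train, test_set = sets$test)
}

#' Train the bar network (Simulation-1 protocol)
#'
#' Trains the single-field bar network on the 8 moving-bar sequences and
#' extracts its direction map.
#'
#' @param seed master seed.
#' @param epochs epoch cap (`NULL` = preset cap of 500; saturation stopping
#'   applies).
#' @param rule a [learning_rule()]; pass mode `"symmetric"` for the
#'   temporally symmetric control.
#' @return a list with `network`, `report` and `map`.
#' @export
run_bar_training <- function(seed = 1, epochs = NULL,
                             rule = learning_rule()) {
  preset <- load_preset("bar_v1")
  net <- new_network(preset, seed = seed)
  fit <- train_layer(net, 1, bar_training_set(), epochs = epochs,
                     seed = seed + 11, rule = rule)
  map <- preferred_directions(fit$network, bar_probe_set(fit$network), 1)
  list(network = fit$network, report = fit$report, map = map)
}

write_json_metrics <- function(x, path) {
  jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Run a configured experiment end to end
#'
#' Thin experiment runner tying the modules together: resolves a preset,
#' trains each field layer-wise on its protocol's stimuli, extracts the
#' preference map and decoder metrics, and writes the whole bundle
#' (resolved config JSON, field weights, map CSV, metrics JSON, figures)
#' under `out_dir`. Deterministic under the config's seed.
#'
#' @param config a list: `preset` (name), `seed`, `epochs` (vector per
#'   field or `NULL`), `rule_mode` (`"asymmetric"`/`"symmetric"`),
#'   `perceptron_epochs` (RDS protocol only).
#' @param out_dir output directory (created).
#' @return invisibly, the metrics list that was written.
#' @export
run_experiment <- function(config, out_dir) {
  stopifnot(is.list(config), !is.null(config$preset))
  preset <- load_preset(config$preset)  # errors before any compute
  seed <- config$seed %||% 1
  rule <- learning_rule(config$rule_mode %||% "asymmetric")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  resolved <- list(preset = preset$name, seed = seed, rule_mode = rule$mode,
                   epochs = config$epochs,
                   perceptron_epochs = config$perceptron_epochs %||% 300,
                   package_version = as.character(utils::packageVersion("nfmotion")))
  write_json_metrics(resolved, file.path(out_dir, "config.json"))

  if (preset$name == "rds_translate") {
    res <- run_rds_decoding(
      seed = seed, epochs_nf1 = config$epochs[1] %||% NULL,
      epochs_nf2 = config$epochs[2] %||% NULL,
      perceptron_epochs = config$perceptron_epochs %||% 300)
    net <- res$network
    probes <- lapply(c(0, 90, 180, 270), function(d)
      make_rds_translation(make_rds_configuration(seed * 1000 + 1), d))
    metrics <- list(train_accuracy = res$train_accuracy,
                    test_accuracy = res$test_accuracy,
                    epochs_run = vapply(res$reports, function(r)
                      r$epochs_run, numeric(1)))
    reports <- res$reports
    utils::write.csv(tidy(res$decoder),
                     file.path(out_dir, "decoder_error_trace.csv"),
                     row.names = FALSE)
  } else {
    sets <- switch(preset$name,
      bar_v1 = list(bar_training_set()),
      grating_plaid = list(grating_training_set(), plaid_training_set()),
      square = list(square_training_set(), square_training_set()))
    net <- new_network(preset, seed = seed)
    reports <- list()
    for (k in seq_along(net$fields)) {
      fit <- train_layer(net, k, sets[[k]], epochs = config$epochs[k] %||% NULL,
                         seed = seed + 11 * k, rule = rule)
      net <- fit$network
      reports[[k]] <- fit$report
    }
    probes <- sets[[length(sets)]]
    metrics <- list(epochs_run = vapply(reports, function(r) r$epochs_run,
                                        numeric(1)))
  }
  map <- preferred_directions(net, probes)
  metrics$directions_covered <- length(unique(map$preferred_deg))
  metrics$opposite_adjacency <- opposite_adjacency_fraction(map)
  utils::write.csv(as.data.frame(map), file.path(out_dir, "direction_map.csv"),
                   row.names = FALSE)
  for (k in seq_along(net$fields))
    save_field(net$fields[[k]], file.path(out_dir, sprintf("field%d.rds", k)))
  ggplot2::ggsave(file.path(out_dir, "direction_map.png"), plot(map),
                  width = 6, height = 5, dpi = 120)
  write_json_metrics(metrics, file.path(out_dir, "metrics.json"))
  invisible(metrics)
}

#' Reproduce a published simulation
#'
#' Convenience wrappers around [run_experiment()] for the three studies:
#' direction selectivity from moving bars, pattern selectivity from squares
#' or plaids, and translational-flow decoding from random dots.
#'
#' @param which one of `"simulation1"`, `"simulation2-square"`,
#'   `"simulation2-plaid"`, `"simulation3"`.
#' @param out_dir output directory.
#' @param seed master seed.
#' @param epochs optional per-field epoch caps (scaled-down runs).
#' @param rule_mode `"asymmetric"` (default) or `"symmetric"`.
#' @return invisibly, the metrics list.
#' @export
repro_simulation <- function(which = c("simulation1", "simulation2-square",
                                       "simulation2-plaid", "simulation3"),
                             out_dir, seed = 1, epochs = NULL,
                             rule_mode = "asymmetric") {
  which <- match.arg(which)
  preset <- switch(which, `simulation1` = "bar_v1",
                   `simulation2-square` = "square",
                   `simulation2-plaid` = "grating_plaid",
                   `simulation3` = "rds_translate")
  run_experiment(list(preset = preset, seed = seed, epochs = epochs,
                      rule_mode = rule_mode), out_dir)
}
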