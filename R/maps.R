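#' Topographic direction-preference map
#'
#' Probes a trained network (weights untouched) with one sequence per
#' direction and assigns each neuron of the chosen field the direction
#' whose sequence evokes its maximum settled response, where a neuron's
#' response to a sequence is its maximum settled activity over the frames.
#' Ties go to the lowest direction angle, deterministically.
#'
#' @param network a trained `layered_network`.
#' @param probe_sequences list of `stimulus_sequence`, typically one per
#'   direction.
#' @param layer which field to map (default the top one).
#' @return a tibble of class `direction_map` with one row per neuron:
#'   `row`, `col`, `preferred_deg`, `peak` (the maximal settled activity,
#'   in \[0, 1\]).
#' @export
preferred_directions <- function(network, probe_sequences,
                                 layer = length(network$fields)) {
  if (length(probe_sequences) == 0) abort("empty probe set")
  dirs <- vapply(probe_sequences, function(s) as.numeric(s$direction_deg),
                 numeric(1))
  ord <- order(dirs)  # ascending angles => which.max tie-breaks to lowest
  probe_sequences <- probe_sequences[ord]
  dirs <- dirs[ord]
  resp <- vapply(probe_sequences, function(s) {
    act <- present_sequence(network, s, upto = layer)$activity[[layer]]
    apply(act, 2, max)
  }, numeric(network$fields[[layer]]$params$dim^2))
  best <- max.col(resp, ties.method = "first")
  dim <- network$fields[[layer]]$params$dim
  g <- sheet_coords(dim)
  out <- tibble(row = g$row, col = g$col,
                preferred_deg = dirs[best],
                peak = resp[cbind(seq_len(dim^2), best)])
  class(out) <- c("direction_map", class(out))
  attr(out, "sheet_dim") <- dim
  attr(out, "probe_directions") <- dirs
  out
}

#' Robustness index
#'
#' One minus the fraction of neurons whose preferred direction differs
#' between a reference map and a perturbed map over the same sheet: 1 when
#' nothing changed, 0 when every neuron deviated.
#'
#' @param reference_map,perturbed_map `direction_map` tibbles over the same
#'   sheet.
#' @return scalar in \[0, 1\].
#' @export
robustness_index <- function(reference_map, perturbed_map) {
  if (nrow(reference_map) != nrow(perturbed_map))
    abort("maps cover different sheets")
  1 - mean(reference_map$preferred_deg != perturbed_map$preferred_deg)
}

# default clean probe set for a trained bar network
bar_probe_set <- function(network, bar_len = 30)
  bar_training_set(image_size = network$image_size, bar_len = bar_len)

#' Input-noise robustness sweep
#'
#' Probes an already-trained network (no retraining) with increasingly
#' noisy moving-bar stimuli and records, per noise level, the robustness
#' index of the resulting preference map against the clean-stimulus
#' reference map.
#'
#' @param network a trained bar network.
#' @param noise_kind `"salt_pepper"` (densities) or `"gaussian"`
#'   (variances).
#' @param levels noise levels; defaults to the published sweeps
#'   (salt-and-pepper density 0.01 to 0.99, Gaussian variance 0.02 to 1,
#'   both in steps of 0.02).
#' @param seed RNG seed for the noise.
#' @param layer field to map.
#' @return a tibble of class `robustness_curve` with columns `level`, `ri`,
#'   `deviated` (neurons changed) and attribute `noise_kind`.
#' @export
run_noise_sweep <- function(network,
                            noise_kind = c("salt_pepper", "gaussian"),
                            levels = NULL, seed = 1,
                            layer = length(network$fields)) {
  noise_kind <- match.arg(noise_kind)
  levels <- levels %||% switch(noise_kind,
    salt_pepper = seq(0.01, 0.99, by = 0.02),
    gaussian = seq(0.02, 1, by = 0.02))
  probes <- bar_probe_set(network)
  ref <- preferred_directions(network, probes, layer)
  n <- nrow(ref)
  rows <- lapply(seq_along(levels), function(i) {
    noisy <- lapply(seq_along(probes), function(j) {
      s <- probes[[j]]
      lev <- levels[i]
      if (lev == 0) s
      else if (noise_kind == "salt_pepper")
        add_salt_pepper_noise(s, lev, seed = seed + 1000 * i + j)
      else add_gaussian_noise(s, lev, seed = seed + 1000 * i + j)
    })
    m <- preferred_directions(network, noisy, layer)
    tibble(level = levels[i], ri = robustness_index(ref, m),
           deviated = round((1 - robustness_index(ref, m)) * n))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_curve", class(out))
  attr(out, "noise_kind") <- noise_kind
  out
}

#' Noise-in-training convergence trials
#'
#' Repeatedly retrains a fresh bar network on noise-corrupted training
#' stimuli and judges, per trial and noise level, whether training
#' converged to a valid motion representation: at least `min_covered` of
#' the probe directions are represented in the resulting preference map
#' (the machine-checkable version of judging the map by inspection; the
#' default of 6/8 is calibrated so that noise-free training counts as
#' converged reliably — exact full coverage is itself a stochastic event
#' at practical epoch budgets). Whether the saturation stopping
#' criterion also fired within the epoch cap is reported alongside but
#' does not enter the verdict: in the bubble-forming regime the
#' per-epoch weight drift plateaus above the saturation tolerance, so a
#' saturation-based verdict would be uniformly negative regardless of
#' noise.
#'
#' @param preset_name network preset to retrain (default `"bar_v1"`).
#' @param noise_kind `"salt_pepper"` or `"gaussian"`.
#' @param levels noise levels to test (one retraining per trial x level).
#' @param n_trials number of independent trials.
#' @param seed base seed; each trial x level gets a distinct derived seed.
#' @param epochs epoch cap per retraining (scaled-down runs pass a smaller
#'   cap than the preset's).
#' @param min_covered how many of the 8 probe directions must be
#'   represented for a trial to count as converged.
#' @return a tibble with one row per trial x level: `trial`, `level`,
#'   `saturated`, `directions_covered`, `converged`.
#' @export
run_noise_training_trials <- function(preset_name = "bar_v1",
                                      noise_kind = c("salt_pepper", "gaussian"),
                                      levels, n_trials = 20, seed = 1,
                                      epochs = NULL, min_covered = 6) {
  noise_kind <- match.arg(noise_kind)
  preset <- load_preset(preset_name)
  rows <- list()
  for (trial in seq_len(n_trials)) {
    for (li in seq_along(levels)) {
      lev <- levels[li]
      sd0 <- seed + 7919 * trial + 131 * li
      train_set <- lapply(seq_along(DIRECTIONS8), function(j) {
        s <- make_moving_bar(DIRECTIONS8[j], image_size = preset$image_size)
        if (lev == 0) s
        else if (noise_kind == "salt_pepper")
          add_salt_pepper_noise(s, lev, seed = sd0 + j)
        else add_gaussian_noise(s, lev, seed = sd0 + j)
      })
      net <- new_network(preset, seed = sd0)
      fit <- train_layer(net, 1, train_set, epochs = epochs, seed = sd0)
      map <- preferred_directions(fit$network, bar_probe_set(fit$network), 1)
      covered <- length(unique(map$preferred_deg))
      rows[[length(rows) + 1]] <- tibble(
        trial = trial, level = lev,
        saturated = fit$report$converged,
        directions_covered = covered,
        converged = covered >= min_covered)
    }
  }
  do.call(rbind, rows)
}

#' Bar-length robustness sweep
#'
#' Probes a network trained on length-30 bars with bars of other lengths
#' and reports the robustness index of each length's map against the
#' length-30 reference map.
#'
#' @param network a trained bar network.
#' @param lengths bar lengths to probe.
#' @param layer field to map.
#' @return a tibble of class `robustness_curve` with columns `length`,
#'   `ri`, `deviated`.
#' @export
run_bar_length_sweep <- function(network, lengths = 15:35,
                                 layer = length(network$fields)) {
  ref <- preferred_directions(network, bar_probe_set(network, 30), layer)
  rows <- lapply(lengths, function(L) {
    m <- preferred_directions(network, bar_probe_set(network, L), layer)
    tibble(length = L, ri = robustness_index(ref, m),
           deviated = round((1 - robustness_index(ref, m)) * nrow(ref)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("robustness_curve", class(out))
  attr(out, "noise_kind") <- "bar_length"
  out
}

#' Fraction of patch boundaries separating opposite directions
#'
#' Qualitative summary of the published observation that patches selective
#' to one direction tend to abut patches selective to the opposite
#' direction: among 4-neighbour pairs of neurons with different preferred
#' directions, the fraction whose preferences differ by exactly 180
#' degrees.
#'
#' @param map a `direction_map`.
#' @return scalar in \[0, 1\] (NaN if the map has a single patch).
#' @export
opposite_adjacency_fraction <- function(map) {
  dim <- attr(map, "sheet_dim")
  pref <- matrix(map$preferred_deg[order(map$col, map$row)], dim, dim)
  diffs <- c()
  h <- cbind(as.vector(pref[, -dim]), as.vector(pref[, -1]))
  v <- cbind(as.vector(pref[-dim, ]), as.vector(pref[-1, ]))
  pairs <- rbind(h, v)
  pairs <- pairs[pairs[, 1] != pairs[, 2], , drop = FALSE]
  if (nrow(pairs) == 0) return(NaN)
  mean((abs(pairs[, 1] - pairs[, 2]) %% 360) == 180)
}
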