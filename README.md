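# nfmotion

Hierarchical neural-field simulation of motion processing in the visual
cortex, with temporally asymmetric Hebbian plasticity.

## The problem

Neurons along the dorsal visual pathway become selective to visual
motion: V1 cells encode the local direction of moving features, MT cells
integrate those cues into the true direction of whole patterns (solving
the aperture problem), and MST cells respond to optic-flow fields such
as coherent translation. `nfmotion` implements a self-organizing model
of how this selectivity can *develop*: sheets of rate neurons ("neural
fields") with short-range lateral excitation and long-range lateral
inhibition, stacked input → NF1 (→ NF2), whose connections adapt by
Hebbian learning with divisive normalization while synthetic moving
stimuli (bars, edges, gratings, plaids, squares, random-dot fields) play
frame by frame.

The core mechanism is an **asymmetric Hebbian rule** on the lateral
connections — a rate-based analogue of spike-timing-dependent
plasticity:

```
ΔW[i←k](t) = α · max(0, η_i(t) − η_i(t−1)) · η_k(t−1)
```

presynaptic activity at the previous frame, paired with the rectified
*increase* of postsynaptic activity at the current frame. Connections
pointing forward along a motion trajectory are potentiated, their
reversals are not, and the recurrent circuit becomes a direction
detector even though the network only ever sees the current frame.
A symmetric control rule is included to show that this temporal
asymmetry — not lateral plasticity in general — is what produces
direction selectivity.

The package is aimed at computational-neuroscience users who want to
reproduce, probe or extend this class of self-organizing map models:
every stage (stimulus generators, field dynamics, plasticity, training
protocol, topographic map extraction, robustness analyses, perceptron
readout) is an exported, documented, seeded function.

## Worked example

Train the single-field V1 model on the eight moving-bar sequences and
extract its direction-preference map:

```r
library(nfmotion)

net <- new_network(load_preset("bar_v1"), seed = 1)
fit <- train_layer(net, 1, bar_training_set(), epochs = 150, seed = 12)
glance(fit$report)
#> # A tibble: 1 × 4
#>   layer epochs_run converged final_saturation
#>   <dbl>      <int> <lgl>                <dbl>
#> 1     1        150 FALSE               0.654

map <- preferred_directions(net, bar_training_set())
table(map$preferred_deg)
#>
#>   0  45  90 135 180 225 270 315
#> 116  97  15  91  55   8  17   1
plot(map)   # quiver map of per-neuron preferred directions
```

Every one of the eight motion directions is claimed by at least one
neuron (population sizes vary run to run; full eight-direction coverage
is itself stochastic at this training length), and patches preferring
opposite directions tend to sit next to each other — the map structure
reported for direction-selectivity maps in visual cortex. The `peak`
column holds each neuron's maximal settled response (arrow length in
the plot). `final_saturation` is the fraction of weights that changed
by less than the saturation tolerance over the last epoch; the lateral
circuitry keeps adapting as long as bubbles keep moving, so training
here stops at the epoch cap rather than at saturation.

Decode translational flow from the two-field random-dot model:

```r
res <- run_rds_decoding(seed = 42, epochs_nf1 = 20, epochs_nf2 = 12)
res$train_accuracy   # fraction of the 80 training sequences decoded
#> [1] 0.6375
res$test_accuracy    # fraction of the 20 held-out dot configurations
#> [1] 0.35
```

(Decoding through NF2 is the model's weak point in this implementation
— the methods vignette's limitations section explains why; a readout of
NF1 instead classifies the training split perfectly and generalizes
well above chance.)

Robustness of a trained bar network to input noise:

```r
curve <- run_noise_sweep(net, "salt_pepper", levels = seq(0.01, 0.99, 0.1))
plot(curve)          # robustness index vs noise density
```

## Package tour

| area | functions |
|---|---|
| stimuli | `make_moving_bar/edge/grating/plaid/square`, `make_rds_configuration/translation`, `add_salt_pepper_noise`, `add_gaussian_noise`, `*_training_set`, `stimulus_manifest` |
| field dynamics | `field_params`, `new_field`, `afferent_response`, `settle`, `reset_activity`, `sigma_pl`, `derive_dim` |
| plasticity | `learning_rule`, `afferent_delta`, `lateral_delta_asymmetric/symmetric`, `divisive_normalize`, `apply_frame_update` |
| networks | `load_preset`, `new_network`, `present_sequence`, `train_layer`, `saturation_fraction`, `clone_network` |
| maps & robustness | `preferred_directions`, `robustness_index`, `run_noise_sweep`, `run_noise_training_trials`, `run_bar_length_sweep`, `opposite_adjacency_fraction` |
| decoding | `new_perceptron`, `perceptron_forward`, `train_perceptron`, `decode_accuracy`, `nf_features` |
| experiments | `run_experiment`, `repro_simulation`, `run_bar_training`, `run_rds_decoding` |

Result objects are tibbles (`direction_map`, `robustness_curve`,
training reports) with `plot()`/`autoplot()` methods and broom-style
`tidy()`/`glance()`. Fields and networks are mutable (environment-backed)
because training updates multi-megabyte weight matrices in place; use
`clone_network()` for snapshots. A thin command-line front end over the
same functions ships in `inst/cli/nfmotion.R`.

Output formats: weights as `.rds` archives, maps and curves as CSV,
metrics as JSON, figures as PNG (see `run_experiment()`).

The methods vignette (`vignettes/nfmotion-methods.Rmd`) documents the
model equations, the stimulus constructions, every tunable parameter
with its default and rationale — including the stability argument that
fixes the sigmoid thresholds the published parameter tables leave
open — and what the synthetic stimuli do and do not emulate.
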