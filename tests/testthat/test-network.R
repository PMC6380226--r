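# small two-field toy network: 4x4 image -> 2x2 field -> 1x1 field
toy_preset <- function() {
  list(fields = list(
    field_params(dim = 2, rf = 2, input_size = 4, r_exc = 1, r_inhb = 2,
                 gamma_exc = 0.5, gamma_inhb = 1, settling_steps = 2),
    field_params(dim = 1, rf = 2, input_size = 2, r_exc = 0.5, r_inhb = 1,
                 gamma_exc = 0, gamma_inhb = 0, settling_steps = 2)),
    image_size = 4)
}

toy_sequence <- function(n_frames = 3, seed = 1) {
  set.seed(seed)
  frames <- lapply(seq_len(n_frames), function(t) matrix(runif(16), 4, 4))
  nfmotion:::new_stimulus_sequence(frames, 0, "bar")
}

test_that("presets reproduce the published parameter table", {
  p <- load_preset("bar_v1")
  f <- p$fields[[1]]
  expect_equal(f$dim, 20L); expect_equal(f$rf, 64L)
  expect_equal(f$r_exc, 3); expect_equal(f$r_inhb, 10)
  expect_equal(f$gamma_exc, 3.9); expect_equal(f$settling_steps, 10L)
  expect_equal(f$epochs, 500L)
  r <- load_preset("rds_translate")
  expect_equal(r$fields[[1]]$dim, 29L)
  expect_equal(r$fields[[1]]$rf, 4L)
  expect_equal(r$fields[[1]]$gamma_aff, 0.3)
  expect_equal(r$fields[[1]]$gamma_exc, 0.68)
  expect_true(r$fields[[1]]$freeze_afferent)
  expect_equal(r$fields[[2]]$dim, 22L)
  expect_equal(r$fields[[2]]$rf, 8L)
  expect_equal(r$fields[[2]]$gamma_exc, 15.68)
  expect_equal(r$fields[[1]]$epochs, 200L)
  s <- load_preset("square")
  expect_equal(s$fields[[1]]$dim, 13L)
  expect_equal(s$fields[[2]]$dim, 15L)
  expect_equal(s$fields[[1]]$alpha_aff, 0.3)
  expect_error(load_preset("nope"))
})

test_that("network assembly checks the geometry chain", {
  net <- new_network(toy_preset(), seed = 1)
  expect_length(net$fields, 2)
  bad <- toy_preset()
  bad$fields[[2]]$input_size <- 3L
  expect_error(new_network(bad), "expects")
})

test_that("presentation without learning leaves weights bit-identical", {
  net <- new_network(toy_preset(), seed = 2)
  snap <- lapply(net$fields, function(f)
    list(a = f$W_aff + 0, e = f$W_exc + 0, i = f$W_inhb + 0))
  out <- present_sequence(net, toy_sequence())
  for (k in 1:2) {
    expect_identical(net$fields[[k]]$W_aff, snap[[k]]$a)
    expect_identical(net$fields[[k]]$W_exc, snap[[k]]$e)
    expect_identical(net$fields[[k]]$W_inhb, snap[[k]]$i)
  }
  expect_length(out$activity, 2)
  expect_equal(dim(out$activity[[1]]), c(3, 4))
  expect_equal(dim(out$activity[[2]]), c(3, 1))
})

test_that("activity chain equals hand-composed afferent/settle calls", {
  net <- new_network(toy_preset(), seed = 3)
  s <- toy_sequence(n_frames = 2, seed = 5)
  out <- present_sequence(net, s)
  f1 <- clone_field(net$fields[[1]]); reset_activity(f1)
  f2 <- clone_field(net$fields[[2]]); reset_activity(f2)
  for (t in 1:2) {
    e1 <- settle(f1, afferent_response(f1, s$frames[[t]]), f1$eta)
    f1$eta <- e1
    e2 <- settle(f2, afferent_response(f2, matrix(e1, 2, 2)), f2$eta)
    f2$eta <- e2
    expect_equal(out$activity[[1]][t, ], e1, tolerance = 1e-12)
    expect_equal(out$activity[[2]][t, ], e2, tolerance = 1e-12)
  }
})

test_that("one-frame sequences trigger no lateral learning (asymmetric)", {
  net <- new_network(toy_preset(), seed = 4)
  w0 <- net$fields[[1]]$W_exc + 0
  present_sequence(net, toy_sequence(n_frames = 1), learn_layer = 1)
  expect_equal(net$fields[[1]]$W_exc, w0, tolerance = 1e-14)
})

test_that("saturation fraction counts near-zero weight changes", {
  expect_equal(saturation_fraction(numeric(10), 1e-6), 1)
  expect_equal(saturation_fraction(rep(1, 4), 0.5), 0)
  expect_equal(saturation_fraction(c(0, 0, 0, 1), 0.5), 0.75)
  expect_error(saturation_fraction(1, 0), "epsilon")
})

test_that("zero-epoch training changes nothing and reports empty", {
  net <- new_network(toy_preset(), seed = 5)
  w0 <- net$fields[[1]]$W_aff + 0
  fit <- train_layer(net, 1, list(toy_sequence()), epochs = 0)
  expect_identical(net$fields[[1]]$W_aff, w0)
  expect_equal(fit$report$epochs_run, 0)
  expect_equal(nrow(fit$report$trace), 0)
})

test_that("all-zero stimuli leave weights unchanged and saturate at once", {
  net <- new_network(toy_preset(), seed = 6)
  w0 <- net$fields[[1]]$W_aff + 0
  zeros <- nfmotion:::new_stimulus_sequence(
    replicate(3, matrix(0, 4, 4), simplify = FALSE), 0, "bar")
  fit <- train_layer(net, 1, list(zeros), epochs = 5)
  expect_equal(net$fields[[1]]$W_aff, w0, tolerance = 1e-12)
  expect_true(fit$report$converged)
  expect_equal(fit$report$epochs_run, 1)
})

test_that("training one layer never touches another layer's weights", {
  net <- new_network(toy_preset(), seed = 7)
  w1 <- net$fields[[1]]$W_aff + 0
  train_layer(net, 2, list(toy_sequence()), epochs = 2)
  expect_identical(net$fields[[1]]$W_aff, w1)
  w2 <- lapply(c("W_aff", "W_exc", "W_inhb"), function(n)
    get(n, net$fields[[2]]) + 0)
  train_layer(net, 1, list(toy_sequence()), epochs = 2)
  expect_identical(net$fields[[2]]$W_aff, w2[[1]])
  expect_identical(net$fields[[2]]$W_exc, w2[[2]])
  expect_identical(net$fields[[2]]$W_inhb, w2[[3]])
})

test_that("identical seed, preset and data give identical final weights", {
  seqs <- list(toy_sequence(seed = 1), toy_sequence(seed = 2))
  run <- function() {
    net <- new_network(toy_preset(), seed = 11)
    train_layer(net, 1, seqs, epochs = 3, seed = 99)
    net$fields[[1]]$W_aff
  }
  expect_identical(run(), run())
})

test_that("training reports tidy into per-epoch traces", {
  net <- new_network(toy_preset(), seed = 8)
  fit <- train_layer(net, 1, list(toy_sequence()), epochs = 2)
  tr <- tidy(fit$report)
  expect_true(all(c("epoch", "mean_dw_exc", "saturation_fraction") %in%
                  names(tr)))
  g <- glance(fit$report)
  expect_equal(g$layer, 1)
  expect_true(g$final_saturation >= 0 && g$final_saturation <= 1)
})
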