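test_that("piecewise-linear sigmoid clamps and is identity on its ramp", {
  expect_equal(sigma_pl(0), 0)
  expect_equal(sigma_pl(1), 1)
  expect_equal(sigma_pl(-5), 0)
  expect_equal(sigma_pl(7), 1)
  expect_equal(sigma_pl(0.3), 0.3)
  # custom thresholds rescale the ramp
  expect_equal(sigma_pl(2, lo = 1, hi = 3), 0.5)
  expect_equal(sigma_pl(matrix(c(-1, 0.25, 2), 1)), matrix(c(0, 0.25, 1), 1))
})

test_that("sheet dimension follows the sliding-window formula", {
  expect_equal(derive_dim(64, 64, 1), 1)
  expect_equal(derive_dim(16, 4, 4), 4)
  expect_equal(derive_dim(64, 12, 4), 14)
  expect_equal(derive_dim(32, 4, 1), 29)  # random-dot NF1 geometry
  expect_equal(derive_dim(29, 8, 1), 22)  # random-dot NF2 geometry
  expect_equal(derive_dim(64, 24, 4), 11)
  expect_error(derive_dim(64, 24, 3), "divisible")
})

test_that("field construction satisfies the weight invariants", {
  f <- tiny_field()
  expect_true(all(f$W_aff >= 0))
  expect_equal(rowSums(f$W_aff), rep(1, 16), tolerance = 1e-12)
  expect_equal(rowSums(f$W_exc), rep(1, 16), tolerance = 1e-12)
  expect_equal(rowSums(f$W_inhb), rep(1, 16), tolerance = 1e-12)
  # lateral support is exactly the configured disc / annulus, no self-loops
  expect_true(all(f$W_exc[f$mask_exc == 0] == 0))
  expect_true(all(f$W_inhb[f$mask_inhb == 0] == 0))
  expect_true(all(diag(f$mask_exc) == 0))
  expect_true(all(diag(f$mask_inhb) == 0))
  expect_equal(sum(f$mask_exc * f$mask_inhb), 0)  # disjoint supports
})

test_that("lateral masks use the configured metric and radii", {
  m <- nfmotion:::lateral_masks(5, 1.5, 3, "euclidean")
  g <- nfmotion:::sheet_coords(5)
  d <- sqrt(outer(g$row, g$row, "-")^2 + outer(g$col, g$col, "-")^2)
  expect_identical(m$exc > 0, d > 0 & d <= 1.5)
  expect_identical(m$inhb > 0, d > 1.5 & d <= 3)
  mc <- nfmotion:::lateral_masks(5, 1, 2, "chebyshev")
  dc <- pmax(abs(outer(g$row, g$row, "-")), abs(outer(g$col, g$col, "-")))
  expect_identical(mc$exc > 0, dc > 0 & dc <= 1)
})

test_that("afferent response matches the per-neuron loop oracle", {
  for (seed in 1:3) {
    f <- tiny_field(dim = 3, rf = 2, input_size = 6, seed = seed)
    x <- rand_input(6, seed + 50)
    expect_equal(afferent_response(f, x), oracle_afferent(f, x),
                 tolerance = 1e-10)
  }
  # shared full-field RF path
  fs <- tiny_field(dim = 3, rf = 6, input_size = 6, seed = 4)
  x <- rand_input(6, 60)
  expect_true(fs$shared_rf)
  expect_equal(afferent_response(fs, x), oracle_afferent(fs, x),
               tolerance = 1e-10)
})

test_that("afferent response edge cases and geometry errors", {
  f <- tiny_field(dim = 3, rf = 2, input_size = 6)
  expect_equal(afferent_response(f, matrix(0, 6, 6)), rep(0, 9))
  f$W_aff[] <- 0
  expect_equal(afferent_response(f, rand_input(6, 1)), rep(0, 9))
  expect_error(afferent_response(f, matrix(0, 5, 5)), "6x6")
})

test_that("settling matches the nested-loop oracle", {
  for (seed in 1:3) {
    f <- tiny_field(dim = 4, rf = 3, input_size = 6, seed = seed,
                    settling_steps = 2)
    S <- runif(16)
    eta0 <- runif(16)
    expect_equal(settle(f, S, eta0), oracle_settle(f, S, eta0),
                 tolerance = 1e-10)
  }
})

test_that("settling with zero lateral gains is the identity on S", {
  f <- tiny_field(dim = 4, rf = 3, input_size = 6, gamma_exc = 0,
                  gamma_inhb = 0, settling_steps = 7)
  S <- runif(16)
  expect_equal(settle(f, S, numeric(16)), S, tolerance = 1e-12)
  # zero afferent drive from the reset state stays silent
  expect_equal(settle(tiny_field(), numeric(16)), rep(0, 16))
})

test_that("settled activity is bounded in [0,1] for arbitrary inputs", {
  for (seed in 1:5) {
    f <- tiny_field(dim = 5, rf = 3, input_size = 7, seed = seed,
                    gamma_exc = 5, gamma_inhb = 0.3, settling_steps = 10)
    set.seed(seed)
    eta <- settle(f, runif(25, 0, 3), runif(25))
    expect_true(all(eta >= 0 & eta <= 1))
  }
})

test_that("activity reset zeroes both grids and is idempotent", {
  f <- tiny_field()
  f$eta <- runif(16); f$eta_prev <- runif(16)
  reset_activity(f)
  expect_equal(f$eta, numeric(16))
  expect_equal(f$eta_prev, numeric(16))
  reset_activity(f)
  expect_equal(f$eta_prev, numeric(16))
  # after a reset the asymmetric rule's presynaptic factor is zero, so a
  # first-frame update cannot change lateral weights
  w0 <- f$W_exc + 0
  apply_frame_update(f, learning_rule("asymmetric"), rand_input(6, 3),
                     runif(16))
  expect_equal(f$W_exc, w0, tolerance = 1e-14)
})

test_that("fields clone deeply and serialize round-trip", {
  f <- tiny_field()
  g <- clone_field(f)
  apply_frame_update(f, learning_rule(), rand_input(6, 8), runif(16))
  expect_false(identical(f$W_aff, g$W_aff))  # original trained on
  path <- tempfile(fileext = ".rds")
  save_field(f, path)
  h <- load_field(path)
  expect_equal(h$W_aff, f$W_aff)
  expect_equal(h$params, f$params)
  unlink(path)
})
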