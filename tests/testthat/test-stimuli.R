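directions8 <- seq(0, 315, by = 45)

test_that("moving bar matches its geometric specification", {
  s <- make_moving_bar(0)
  validate_sequence(s)
  expect_length(s$frames, 8)
  # frame 1: a vertical 30 x 2 bar (60 lit pixels), columns contiguous
  f1 <- s$frames[[1]]
  expect_equal(sum(f1), 60)
  lit_cols <- which(colSums(f1) > 0)
  expect_length(lit_cols, 2)
  expect_equal(diff(lit_cols), 1)
  expect_equal(sum(colSums(f1) == 30), 2)
  # column centre of mass advances ~7.8 px per frame (within rounding)
  com <- vapply(s$frames, function(f) sum(col(f) * f) / sum(f), numeric(1))
  expect_true(all(abs(diff(com) - 7.8) <= 1))
})

test_that("bar generator handles degenerate and invalid inputs", {
  s0 <- make_moving_bar(90, step_px = 0)
  expect_true(all(vapply(s0$frames[-1], identical, logical(1),
                         y = s0$frames[[1]])))
  expect_error(make_moving_bar(30), "direction")
  expect_error(make_moving_bar(0, bar_len = 100), "bar_len")
})

test_that("all eight bar directions produce valid in-frame sequences", {
  for (d in directions8) {
    s <- make_moving_bar(d)
    validate_sequence(s)
    expect_true(all(vapply(s$frames, sum, numeric(1)) > 0), info = d)
  }
})

test_that("moving edge fills the half-plane one pixel per frame", {
  s <- make_moving_edge("L2R")
  expect_length(s$frames, 64)
  for (t in c(1, 7, 64))
    expect_equal(sum(colSums(s$frames[[t]]) == 64), t)
  # top-to-bottom is the transpose of left-to-right, frame by frame
  tb <- make_moving_edge("T2B")
  for (t in c(1, 9, 30))
    expect_identical(tb$frames[[t]], t(s$frames[[t]]))
  one <- make_moving_edge("B2T", n_frames = 1)
  expect_length(one$frames, 1)
})

test_that("grating drifts with period 5 and time-reverses under 180 deg flip", {
  g <- make_moving_grating(0)
  validate_sequence(g)
  expect_length(g$frames, 10)
  # spatial period along the motion axis: row profile repeats every 5 px
  prof <- g$frames[[1]][1, ]
  expect_equal(prof[1:59], prof[6:64], tolerance = 1e-12)
  # direction d and d+180 are the same sequence reversed in time
  for (d in c(0, 45, 90)) {
    a <- make_moving_grating(d)
    b <- make_moving_grating(d + 180)
    for (t in 1:10)
      expect_equal(a$frames[[t]], b$frames[[11 - t]], tolerance = 1e-12)
  }
  expect_error(make_moving_grating(0, spatial_period_px = 1), "period")
})

test_that("plaid composes the two gratings at pattern direction +/- 45", {
  p <- make_moving_plaid(45)
  expect_setequal(p$meta$components, c(0, 90))
  expect_setequal(make_moving_plaid(315)$meta$components, c(270, 0))
  validate_sequence(p)
  # the plaid frame is the mean of its component gratings
  g0 <- make_moving_grating(0); g90 <- make_moving_grating(90)
  expect_equal(p$frames[[3]], (g0$frames[[3]] + g90$frames[[3]]) / 2)
  # superposing a grating with itself returns that grating
  expect_equal((g0$frames[[1]] + g0$frames[[1]]) / 2, g0$frames[[1]])
})

test_that("moving square keeps its full 24x24 area in frame", {
  for (d in directions8) {
    s <- make_moving_square(d)
    expect_length(s$frames, 5)
    expect_true(all(vapply(s$frames, sum, numeric(1)) == 576), info = d)
  }
  # opposite directions through the centre are time reversals
  a <- make_moving_square(0); b <- make_moving_square(180)
  for (t in 1:5) expect_identical(a$frames[[t]], b$frames[[6 - t]])
})

test_that("RDS configuration places one dot per 8x8 block", {
  for (seed in c(1, 17, 99)) {
    cfg <- make_rds_configuration(seed)
    expect_equal(sum(cfg), 64)  # 16 dots x 4 px
    for (bi in 1:4) for (bj in 1:4) {
      blk <- cfg[(bi * 8 - 7):(bi * 8), (bj * 8 - 7):(bj * 8)]
      expect_equal(sum(blk), 4)
    }
  }
  expect_identical(make_rds_configuration(5), make_rds_configuration(5))
})

test_that("RDS translation wraps on the torus and conserves density", {
  cfg <- make_rds_configuration(3)
  s <- make_rds_translation(cfg, 0)
  expect_length(s$frames, 5)
  expect_true(all(vapply(s$frames, sum, numeric(1)) == 64))
  # frame t equals frame 0 shifted t px along the motion axis
  for (t in 2:5) {
    shifted <- cfg[, c((32 - t + 2):32, 1:(32 - t + 1))]
    expect_identical(s$frames[[t]], shifted)
  }
  # 32 unit steps return to the start
  long <- make_rds_translation(cfg, 90, n_frames = 33)
  expect_identical(long$frames[[33]], long$frames[[1]])
  expect_error(make_rds_translation(cfg, 45), "cardinal")
})

test_that("salt-and-pepper noise replaces the stated fraction of pixels", {
  s <- make_moving_bar(0)
  expect_identical(add_salt_pepper_noise(s, 0), s)
  n <- add_salt_pepper_noise(s, 0.02, seed = 7)
  validate_sequence(n)
  changed <- mean(vapply(seq_along(s$frames), function(t)
    sum(n$frames[[t]] != s$frames[[t]]), numeric(1)))
  # density 0.02 replaces ~82 px/frame; about half actually change value
  expect_gt(changed, 20)
  expect_lt(changed, 62)
  sat <- add_salt_pepper_noise(s, 1, seed = 7)
  expect_true(all(unlist(sat$frames) %in% c(0, 1)))
  expect_gt(mean(vapply(seq_along(s$frames), function(t)
    mean(sat$frames[[t]] != s$frames[[t]]), numeric(1))), 0.3)
})

test_that("gaussian noise has the requested variance and clips to [0,1]", {
  s <- make_moving_bar(0)
  n <- add_gaussian_noise(s, variance = 0.04, seed = 11)
  validate_sequence(n)
  rng <- range(unlist(n$frames))
  expect_gte(rng[1], 0); expect_lte(rng[2], 1)
  # interior (unclipped) pixels: empirical variance close to requested
  mid <- make_moving_grating(0)  # values well inside [0,1] mostly
  nm <- add_gaussian_noise(mid, variance = 0.01, seed = 2)
  d <- unlist(nm$frames) - unlist(mid$frames)
  keep <- unlist(nm$frames) > 0 & unlist(nm$frames) < 1
  expect_equal(stats::var(d[keep]), 0.01, tolerance = 0.1)
  expect_identical(add_gaussian_noise(s, 0), s)
})

test_that("training-set builders emit the published counts and splits", {
  expect_length(bar_training_set(), 8)
  expect_length(grating_training_set(), 8)
  expect_length(plaid_training_set(), 8)
  expect_length(square_training_set(), 8)
  sets <- rds_training_sets(seed = 1)
  expect_length(sets$train, 80)
  expect_length(sets$test, 20)
  # split is by configuration: no configuration id appears in both
  cid <- function(ss) unique(vapply(ss, function(s) s$meta$config_id, numeric(1)))
  expect_length(intersect(cid(sets$train), cid(sets$test)), 0)
  man <- stimulus_manifest(sets$test, split = "test")
  expect_equal(nrow(man), 20)
  expect_true(all(man$n_frames == 5))
})

test_that("generators are bit-reproducible under a fixed seed", {
  a <- rds_training_sets(seed = 9); b <- rds_training_sets(seed = 9)
  expect_identical(a$train[[13]]$frames, b$train[[13]]$frames)
  n1 <- add_salt_pepper_noise(make_moving_bar(90), 0.1, seed = 4)
  n2 <- add_salt_pepper_noise(make_moving_bar(90), 0.1, seed = 4)
  expect_identical(n1$frames, n2$frames)
  g1 <- add_gaussian_noise(make_moving_bar(90), 0.3, seed = 4)
  g2 <- add_gaussian_noise(make_moving_bar(90), 0.3, seed = 4)
  expect_identical(g1$frames, g2$frames)
})
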