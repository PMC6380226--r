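#' @useDynLib nfmotion, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort warn
#' @importFrom tibble tibble as_tibble
NULL

# The eight canonical motion directions (degrees). 0 = rightward, 90 = upward
# (decreasing row index), angles increase counter-clockwise.
DIRECTIONS8 <- seq(0, 315, by = 45)

#' Unit displacement vector for a motion direction
#'
#' Frames are row-major grids with x = column increasing rightward and
#' y = row increasing downward, so a direction of `90` degrees (upward
#' motion) corresponds to a *decreasing* row index.
#'
#' @param direction_deg direction of motion in degrees.
#' @return numeric `c(dx, dy)` with `dx` the column and `dy` the row step.
#' @keywords internal
direction_vector <- function(direction_deg) {
  th <- direction_deg * pi / 180
  c(dx = cos(th), dy = -sin(th))
}

new_stimulus_sequence <- function(frames, direction_deg, kind, meta = list()) {
  structure(
    list(frames = frames, direction_deg = direction_deg, kind = kind,
         meta = meta),
    class = "stimulus_sequence"
  )
}

#' Validate a stimulus sequence
#'
#' Checks the invariants shared by every generator: all frames are identical
#' in size, and all intensities lie in \[0, 1\].
#'
#' @param x a `stimulus_sequence`.
#' @return `x`, invisibly; errors on violation.
#' @export
validate_sequence <- function(x) {
  if (!inherits(x, "stimulus_sequence")) abort("not a stimulus_sequence")
  if (length(x$frames) < 1) abort("sequence has no frames")
  dims <- vapply(x$frames, dim, integer(2))
  if (any(dims != dims[, 1])) abort("frames differ in size")
  rng <- range(unlist(lapply(x$frames, range)))
  if (rng[1] < 0 || rng[2] > 1) abort("frame values outside [0, 1]")
  invisible(x)
}

#' @export
print.stimulus_sequence <- function(x, ...) {
  d <- dim(x$frames[[1]])
  cat(sprintf("<stimulus_sequence> kind=%s direction=%s deg, %d frames of %dx%d\n",
              x$kind, format(x$direction_deg), length(x$frames), d[1], d[2]))
  invisible(x)
}

check_direction8 <- function(direction_deg) {
  if (!direction_deg %in% DIRECTIONS8)
    abort(sprintf("direction must be one of %s", paste(DIRECTIONS8, collapse = ", ")))
}

# Rasterize a rectangle of length `len` (perpendicular to motion) and width
# `wid` (along motion) centred at (cx, cy) in pixel coordinates; a pixel is
# lit when its centre falls inside the rotated rectangle.
raster_bar <- function(image_size, cx, cy, direction_deg, len, wid) {
  v <- direction_vector(direction_deg)
  cols <- matrix(rep(seq_len(image_size), each = image_size), image_size)
  rows <- matrix(rep(seq_len(image_size), times = image_size), image_size)
  u <- (cols - cx) * v["dx"] + (rows - cy) * v["dy"]      # along motion
  w <- -(cols - cx) * v["dy"] + (rows - cy) * v["dx"]     # along orientation
  frame <- matrix(0, image_size, image_size)
  # half-open intervals keep the rasterized width/length exact for integer
  # and half-integer centres (a closed interval would light 3 columns for a
  # width-2 bar whenever the centre sits on a pixel column)
  frame[u > -wid / 2 & u <= wid / 2 & w > -len / 2 & w <= len / 2] <- 1
  frame
}

#' Moving-bar stimulus
#'
#' A white bar oriented perpendicular to its direction of motion sweeps
#' across a black background. The default geometry is a 30 x 2 px bar on a
#' 64 x 64 frame moving 7.8 px per frame over 8 frames, covering the frame
#' end to end. Bar centre positions accumulate in floating point and are
#' rasterized per frame (a pixel is lit when its centre falls inside the
#' bar rectangle); no anti-aliasing.
#'
#' @param direction_deg one of 0, 45, ..., 315. 0 degrees is a vertical bar
#'   moving left to right.
#' @param image_size frame side length in pixels.
#' @param bar_len,bar_width bar length (perpendicular to motion) and width
#'   (along motion) in pixels.
#' @param n_frames number of frames.
#' @param step_px displacement of the bar centre per frame, in pixels.
#' @return a `stimulus_sequence` of kind `"bar"`.
#' @export
make_moving_bar <- function(direction_deg, image_size = 64, bar_len = 30,
                            bar_width = 2, n_frames = 8, step_px = 7.8) {
  check_direction8(direction_deg)
  if (bar_len > image_size) abort("bar_len exceeds image_size")
  v <- direction_vector(direction_deg)
  centre <- (image_size + 1) / 2
  # centre the trajectory on the frame midpoint
  t0 <- (n_frames - 1) / 2
  frames <- lapply(seq_len(n_frames) - 1, function(t) {
    cx <- centre + (t - t0) * step_px * v["dx"]
    cy <- centre + (t - t0) * step_px * v["dy"]
    raster_bar(image_size, cx, cy, direction_deg, bar_len, bar_width)
  })
  new_stimulus_sequence(frames, direction_deg, "bar",
                        list(bar_len = bar_len, bar_width = bar_width,
                             step_px = step_px, image_size = image_size))
}

#' Moving-edge stimulus
#'
#' A step edge (a filled half-plane of 1s) advancing one pixel per frame,
#' used as a probe for component-motion selectivity. Directions are the four
#' cardinal sweeps: `"L2R"`, `"R2L"`, `"T2B"`, `"B2T"`. For `"L2R"`, frame
#' `t` has exactly `t` leading columns set to 1.
#'
#' @param direction one of `"L2R"`, `"R2L"`, `"T2B"`, `"B2T"`.
#' @param image_size frame side length.
#' @param n_frames number of frames (default one sweep across the frame).
#' @return a `stimulus_sequence` of kind `"edge"`; `direction_deg` is the
#'   equivalent motion angle (0, 180, 270, 90).
#' @export
make_moving_edge <- function(direction = c("L2R", "R2L", "T2B", "B2T"),
                             image_size = 64, n_frames = 64) {
  direction <- match.arg(direction)
  base <- lapply(seq_len(n_frames), function(t) {
    f <- matrix(0, image_size, image_size)
    f[, seq_len(min(t, image_size))] <- 1
    f
  })
  frames <- switch(direction,
    L2R = base,
    R2L = lapply(base, function(f) f[, rev(seq_len(image_size))]),
    T2B = lapply(base, t),
    B2T = lapply(base, function(f) t(f)[rev(seq_len(image_size)), ]))
  deg <- c(L2R = 0, R2L = 180, T2B = 270, B2T = 90)[[direction]]
  new_stimulus_sequence(frames, deg, "edge", list(direction = direction))
}

# Drifting sinusoid sampled at pixel centres. Temporal phase is centred on
# the middle frame so that direction d and d+180 are exact time-reversals.
grating_frame <- function(image_size, direction_deg, period, phase_px) {
  v <- direction_vector(direction_deg)
  cols <- matrix(rep(seq_len(image_size), each = image_size), image_size)
  rows <- matrix(rep(seq_len(image_size), times = image_size), image_size)
  u <- cols * v["dx"] + rows * v["dy"]
  0.5 + 0.5 * cos(2 * pi * (u - phase_px) / period)
}

#' Drifting sinusoidal grating
#'
#' A sinusoidal luminance grating drifting orthogonally to its orientation
#' at `speed_px` pixels per frame, values in \[0, 1\].
#'
#' @param direction_deg drift direction in degrees (any of the 8 canonical
#'   directions).
#' @param spatial_period_px spatial period of the sinusoid in pixels.
#' @param image_size frame side length.
#' @param n_frames number of frames.
#' @param speed_px drift in pixels per frame.
#' @return a `stimulus_sequence` of kind `"grating"`.
#' @export
make_moving_grating <- function(direction_deg, spatial_period_px = 5,
                                image_size = 64, n_frames = 10,
                                speed_px = 1) {
  if (spatial_period_px <= 1) abort("spatial period must exceed 1 px")
  t0 <- (n_frames - 1) / 2
  frames <- lapply(seq_len(n_frames) - 1, function(t)
    grating_frame(image_size, direction_deg, spatial_period_px,
                  (t - t0) * speed_px))
  new_stimulus_sequence(frames, direction_deg, "grating",
                        list(period = spatial_period_px, speed = speed_px))
}

#' Drifting plaid
#'
#' Superposition (arithmetic mean) of two component gratings of equal period
#' and speed drifting at the pattern direction +/- 45 degrees; the coherent
#' percept moves along `pattern_direction_deg`.
#'
#' @inheritParams make_moving_grating
#' @param pattern_direction_deg direction of coherent pattern motion.
#' @return a `stimulus_sequence` of kind `"plaid"`; `meta$components` holds
#'   the two component directions.
#' @export
make_moving_plaid <- function(pattern_direction_deg, spatial_period_px = 5,
                              image_size = 64, n_frames = 10, speed_px = 1) {
  comps <- (pattern_direction_deg + c(-45, 45)) %% 360
  g <- lapply(comps, make_moving_grating,
              spatial_period_px = spatial_period_px, image_size = image_size,
              n_frames = n_frames, speed_px = speed_px)
  frames <- lapply(seq_len(n_frames), function(t)
    (g[[1]]$frames[[t]] + g[[2]]$frames[[t]]) / 2)
  new_stimulus_sequence(frames, pattern_direction_deg %% 360, "plaid",
                        list(components = comps, period = spatial_period_px,
                             speed = speed_px))
}

#' Moving solid square
#'
#' A white square translating across a black background, its trajectory
#' centred on the frame midpoint so the square passes through the origin of
#' the image and stays fully in frame. Displacements are rounded to whole
#' pixels per axis.
#'
#' @param direction_deg one of the 8 canonical directions.
#' @param square_size side of the square in pixels.
#' @param image_size frame side length.
#' @param n_frames number of frames.
#' @param step_px centre displacement per frame before per-axis rounding.
#' @return a `stimulus_sequence` of kind `"square"`.
#' @export
make_moving_square <- function(direction_deg, square_size = 24,
                               image_size = 64, n_frames = 5, step_px = 8) {
  check_direction8(direction_deg)
  v <- direction_vector(direction_deg)
  step <- round(step_px * v)  # integer per-axis displacement
  centre <- floor((image_size - square_size) / 2) + 1  # top-left when centred
  t0 <- (n_frames - 1) / 2
  frames <- lapply(seq_len(n_frames) - 1, function(t) {
    cx <- centre + round((t - t0) * step[["dx"]])
    cy <- centre + round((t - t0) * step[["dy"]])
    if (cx < 1 || cy < 1 || cx + square_size - 1 > image_size ||
        cy + square_size - 1 > image_size)
      abort("square leaves the frame; reduce step_px or n_frames")
    f <- matrix(0, image_size, image_size)
    f[cy:(cy + square_size - 1), cx:(cx + square_size - 1)] <- 1
    f
  })
  new_stimulus_sequence(frames, direction_deg, "square",
                        list(square_size = square_size, step_px = step_px))
}

#' Random-dot configuration
#'
#' Places 16 dots of 2 x 2 px on a 32 x 32 grid, one dot uniformly at random
#' inside each of the 16 disjoint 8 x 8 blocks (each dot fully inside its
#' block). Deterministic for a given seed.
#'
#' @param seed integer seed for dot placement.
#' @param grid_size frame side (must be a multiple of `block_size`).
#' @param block_size side of the disjoint blocks.
#' @param dot_size side of each square dot.
#' @return a binary `grid_size` x `grid_size` matrix with
#'   `(grid_size/block_size)^2` dots.
#' @export
make_rds_configuration <- function(seed, grid_size = 32, block_size = 8,
                                   dot_size = 2) {
  if (grid_size %% block_size != 0) abort("grid not tiled by blocks")
  nb <- grid_size / block_size
  frame <- matrix(0, grid_size, grid_size)
  rng <- local({ set.seed(seed); list(
    ro = sample.int(block_size - dot_size + 1, nb * nb, replace = TRUE),
    co = sample.int(block_size - dot_size + 1, nb * nb, replace = TRUE)) })
  k <- 0
  for (bi in seq_len(nb)) for (bj in seq_len(nb)) {
    k <- k + 1
    r0 <- (bi - 1) * block_size + rng$ro[k]
    c0 <- (bj - 1) * block_size + rng$co[k]
    frame[r0:(r0 + dot_size - 1), c0:(c0 + dot_size - 1)] <- 1
  }
  frame
}

# circular shift of a matrix by (dr, dc); positive dr moves content down
circshift <- function(m, dr, dc) {
  n <- nrow(m); p <- ncol(m)
  m[((seq_len(n) - 1 - dr) %% n) + 1, ((seq_len(p) - 1 - dc) %% p) + 1]
}

#' Translational random-dot sequence
#'
#' Translates a dot configuration coherently one pixel per frame along a
#' cardinal direction with toroidal wrap-around, so dot density is conserved
#' across frames.
#'
#' @param configuration binary matrix from [make_rds_configuration()].
#' @param direction_deg one of 0, 90, 180, 270.
#' @param n_frames number of frames.
#' @param step_px displacement per frame in pixels.
#' @return a `stimulus_sequence` of kind `"rds_translate"`.
#' @export
make_rds_translation <- function(configuration, direction_deg, n_frames = 5,
                                 step_px = 1) {
  if (!direction_deg %in% c(0, 90, 180, 270))
    abort("RDS translation supports the 4 cardinal directions")
  v <- direction_vector(direction_deg)
  frames <- lapply(seq_len(n_frames) - 1, function(t)
    circshift(configuration, round(t * step_px * v[["dy"]]),
              round(t * step_px * v[["dx"]])))
  new_stimulus_sequence(frames, direction_deg, "rds_translate",
                        list(step_px = step_px))
}

#' Salt-and-pepper corruption
#'
#' Replaces a fraction `density` of the pixels of every frame with values
#' drawn uniformly from \{0, 1\}. On near-binary stimuli about half of the
#' replacements actually change the pixel, so a density of 0.02 on a 64 x 64
#' frame visibly corrupts about 40 pixels.
#'
#' @param sequence a `stimulus_sequence`.
#' @param density fraction of pixels replaced, in \[0, 1\].
#' @param seed RNG seed.
#' @return a corrupted `stimulus_sequence` (same kind and direction;
#'   `meta$noise` records the perturbation).
#' @export
add_salt_pepper_noise <- function(sequence, density, seed = 1) {
  stopifnot(density >= 0, density <= 1)
  if (density == 0) return(sequence)
  set.seed(seed)
  frames <- lapply(sequence$frames, function(f) {
    n <- length(f)
    idx <- sample.int(n, round(density * n))
    f[idx] <- sample(c(0, 1), length(idx), replace = TRUE)
    f
  })
  out <- new_stimulus_sequence(frames, sequence$direction_deg, sequence$kind,
                               sequence$meta)
  out$meta$noise <- list(kind = "salt_pepper", density = density, seed = seed)
  out
}

#' Additive Gaussian noise
#'
#' Adds zero-mean (by default) Gaussian noise per pixel and clips the result
#' to \[0, 1\].
#'
#' @param sequence a `stimulus_sequence`.
#' @param variance noise variance.
#' @param mean noise mean.
#' @param seed RNG seed.
#' @return a corrupted `stimulus_sequence`.
#' @export
add_gaussian_noise <- function(sequence, variance, mean = 0, seed = 1) {
  stopifnot(variance >= 0)
  if (variance == 0 && mean == 0) return(sequence)
  set.seed(seed)
  frames <- lapply(sequence$frames, function(f) {
    g <- f + stats::rnorm(length(f), mean, sqrt(variance))
    pmin(pmax(matrix(g, nrow(f)), 0), 1)
  })
  out <- new_stimulus_sequence(frames, sequence$direction_deg, sequence$kind,
                               sequence$meta)
  out$meta$noise <- list(kind = "gaussian", mean = mean, variance = variance,
                         seed = seed)
  out
}

#' Training-set builders
#'
#' Build the canonical training sets: 8 bar, 8 grating, 8 plaid and 8 square
#' sequences (one per canonical direction), and the translational random-dot
#' corpus of 25 configurations x 4 directions = 100 sequences split 80/20
#' into train/test *by configuration* (20 configurations train, 5 test), so
#' the test set probes generalization to unseen dot layouts.
#'
#' @param seed base seed for the random-dot configurations.
#' @param n_config number of dot configurations.
#' @param n_train_config how many configurations go to the training split.
#' @param ... passed to the underlying generator.
#' @return `bar_training_set()` etc. return a list of `stimulus_sequence`;
#'   `rds_training_sets()` returns `list(train=, test=)`.
#' @name training_sets
NULL

#' @rdname training_sets
#' @export
bar_training_set <- function(...) lapply(DIRECTIONS8, make_moving_bar, ...)

#' @rdname training_sets
#' @export
grating_training_set <- function(...) lapply(DIRECTIONS8, make_moving_grating, ...)

#' @rdname training_sets
#' @export
plaid_training_set <- function(...) lapply(DIRECTIONS8, make_moving_plaid, ...)

#' @rdname training_sets
#' @export
square_training_set <- function(...) lapply(DIRECTIONS8, make_moving_square, ...)

#' @rdname training_sets
#' @export
rds_training_sets <- function(seed = 1, n_config = 25, n_train_config = 20,
                              ...) {
  configs <- lapply(seq_len(n_config), function(i)
    make_rds_configuration(seed + i - 1, ...))
  build <- function(idx) {
    out <- list()
    for (i in idx) for (d in c(0, 90, 180, 270)) {
      s <- make_rds_translation(configs[[i]], d)
      s$meta$config_id <- i
      out[[length(out) + 1]] <- s
    }
    out
  }
  list(train = build(seq_len(n_train_config)),
       test = build(seq(n_train_config + 1, n_config)))
}

#' Stimulus manifest
#'
#' Summarise a list of sequences as a tibble (one row per sequence).
#'
#' @param sequences list of `stimulus_sequence`.
#' @param split optional split label recycled across rows.
#' @return a tibble with columns kind, direction_deg, n_frames, height,
#'   width, split.
#' @export
stimulus_manifest <- function(sequences, split = NA_character_) {
  tibble(
    kind = vapply(sequences, function(s) s$kind, character(1)),
    direction_deg = vapply(sequences, function(s) as.numeric(s$direction_deg), numeric(1)),
    n_frames = vapply(sequences, function(s) length(s$frames), integer(1)),
    height = vapply(sequences, function(s) nrow(s$frames[[1]]), integer(1)),
    width = vapply(sequences, function(s) ncol(s$frames[[1]]), integer(1)),
    split = split
  )
}
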