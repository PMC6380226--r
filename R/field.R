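#' Piecewise-linear sigmoid
#'
#' The squashing nonlinearity used throughout the field dynamics: 0 below
#' `lo`, 1 above `hi`, linear in between. With the defaults `lo = 0`,
#' `hi = 1` it is the identity on \[0, 1\] and a hard clip outside.
#'
#' @param x numeric scalar, vector or matrix.
#' @param lo,hi ramp thresholds (`lo < hi`).
#' @return values in \[0, 1\], same shape as `x`.
#' @export
sigma_pl <- function(x, lo = 0, hi = 1) {
  # first pmax/pmin argument carries the dim attributes through
  pmin(pmax((x - lo) / (hi - lo), 0), 1)
}

#' Neural-field sheet dimension
#'
#' Number of receptive-field positions along one axis when an `rf`-wide
#' window slides over an `image_size`-wide input with the given stride:
#' `(image_size - rf) / stride + 1`.
#'
#' @param image_size input sheet side length.
#' @param rf receptive-field side length.
#' @param stride window displacement between neighbouring neurons.
#' @return integer sheet side length.
#' @export
derive_dim <- function(image_size, rf, stride) {
  stopifnot(stride >= 1, rf <= image_size)
  if ((image_size - rf) %% stride != 0) {
    ok <- Filter(function(s) (image_size - rf) %% s == 0,
                 seq_len(max(1, image_size - rf)))
    abort(sprintf(
      "(image_size - rf) = %d is not divisible by stride %d; valid strides: %s",
      image_size - rf, stride, paste(utils::head(ok, 8), collapse = ", ")))
  }
  as.integer((image_size - rf) / stride + 1)
}

# 0-based RF origin offsets for `dim` neurons along one axis. When an exact
# integer stride exists this reproduces it; otherwise origins are spread as
# evenly as possible (several published sheet sizes admit no integer stride).
rf_offsets <- function(input_size, rf, dim) {
  if (rf > input_size) abort("rf exceeds input size")
  if (dim == 1 || rf == input_size) return(rep(0L, dim))
  as.integer(round(seq(0, input_size - rf, length.out = dim)))
}

#' Field parameter set
#'
#' Bundles every per-field scalar: sheet and receptive-field geometry,
#' lateral radii, gains, learning rates, settling iterations and the
#' training epoch cap.
#'
#' @param dim sheet side length (neurons).
#' @param rf receptive-field side length (input pixels or lower-sheet
#'   neurons).
#' @param input_size side length of the field's input sheet.
#' @param r_exc,r_inhb excitatory / inhibitory lateral radii in neuron
#'   units; excitation acts on `0 < d <= r_exc`, inhibition on the annulus
#'   `r_exc < d <= r_inhb`.
#' @param gamma_aff,gamma_exc,gamma_inhb afferent / excitatory / inhibitory
#'   gains.
#' @param alpha_aff,alpha_exc,alpha_inhb learning rates.
#' @param settling_steps lateral iterations per frame (settling time).
#' @param epochs training epoch cap.
#' @param freeze_afferent if `TRUE` the afferent weights are constants
#'   (used by the random-dot protocol, where they are fixed at 1).
#' @param metric `"euclidean"` (circular neighbourhoods) or `"chebyshev"`
#'   (square neighbourhoods).
#' @param sigma_lo,sigma_hi thresholds of the piecewise-linear sigmoid
#'   used during lateral settling.
#' @param sigma_aff_lo,sigma_aff_hi thresholds for the afferent response;
#'   default the settling thresholds (one shared sigmoid).
#' @return an object of class `field_params`.
#' @export
field_params <- function(dim, rf, input_size, r_exc, r_inhb,
                         gamma_aff = 1, gamma_exc, gamma_inhb = 1,
                         alpha_aff = 0.05, alpha_exc = 0.05,
                         alpha_inhb = 0.05, settling_steps = 10,
                         epochs = 500, freeze_afferent = FALSE,
                         metric = c("euclidean", "chebyshev"),
                         sigma_lo = 0, sigma_hi = 1,
                         sigma_aff_lo = sigma_lo, sigma_aff_hi = sigma_hi) {
  metric <- match.arg(metric)
  stopifnot(r_exc < r_inhb, settling_steps >= 1, dim >= 1, rf >= 1,
            gamma_aff >= 0, gamma_exc >= 0, gamma_inhb >= 0,
            alpha_aff >= 0, alpha_exc >= 0, alpha_inhb >= 0)
  structure(
    list(dim = as.integer(dim), rf = as.integer(rf),
         input_size = as.integer(input_size), r_exc = r_exc, r_inhb = r_inhb,
         gamma_aff = gamma_aff, gamma_exc = gamma_exc,
         gamma_inhb = gamma_inhb, alpha_aff = alpha_aff,
         alpha_exc = alpha_exc, alpha_inhb = alpha_inhb,
         settling_steps = as.integer(settling_steps),
         epochs = as.integer(epochs), freeze_afferent = freeze_afferent,
         metric = metric, sigma_lo = sigma_lo, sigma_hi = sigma_hi,
         sigma_aff_lo = sigma_aff_lo, sigma_aff_hi = sigma_aff_hi),
    class = "field_params")
}

# neuron sheet coordinates in column-major order: index = (col-1)*dim + row
sheet_coords <- function(dim) {
  list(row = rep(seq_len(dim), times = dim),
       col = rep(seq_len(dim), each = dim))
}

# 0/1 lateral support masks (self-connection excluded)
lateral_masks <- function(dim, r_exc, r_inhb, metric = "euclidean") {
  g <- sheet_coords(dim)
  dr <- outer(g$row, g$row, "-")
  dc <- outer(g$col, g$col, "-")
  d <- if (metric == "euclidean") sqrt(dr^2 + dc^2) else pmax(abs(dr), abs(dc))
  list(exc = (d > 0 & d <= r_exc) * 1,
       inhb = (d > r_exc & d <= r_inhb) * 1)
}

# linear-index patch matrix: row i = indices of neuron i's RF inside the
# column-major input matrix
patch_indices <- function(params) {
  off <- rf_offsets(params$input_size, params$rf, params$dim)
  g <- sheet_coords(params$dim)
  rf <- params$rf; isz <- params$input_size
  n <- params$dim^2
  P <- matrix(0L, n, rf * rf)
  for (i in seq_len(n)) {
    rr <- off[g$row[i]] + seq_len(rf)
    cc <- off[g$col[i]] + seq_len(rf)
    P[i, ] <- as.integer(outer(rr, (cc - 1L) * isz, "+"))
  }
  P
}

normalize_rows <- function(W) {
  s <- rowSums(W)
  ok <- s > 0
  W[ok, ] <- W[ok, , drop = FALSE] / s[ok]
  W
}

#' Create a neural field
#'
#' Builds a field's state: afferent weights (uniform random in \[0, 1\],
#' or all 1 when frozen), lateral excitatory/inhibitory weights (uniform
#' random on their distance support), each neuron's incoming weights of
#' each type normalized to unit sum, plus zeroed activity grids.
#'
#' A `neural_field` has *reference semantics*: it is an environment, and
#' training updates its weight matrices in place (a fresh multi-megabyte
#' weight matrix per frame would dominate the simulation cost). Use
#' [clone_field()] to take an independent snapshot.
#'
#' @param params a [field_params()] object.
#' @param seed RNG seed for weight initialization.
#' @return an object of class `neural_field` (an environment).
#' @export
new_field <- function(params, seed = 1) {
  set.seed(seed)
  n <- params$dim^2
  p <- params$rf^2
  masks <- lateral_masks(params$dim, params$r_exc, params$r_inhb,
                         params$metric)
  shared_rf <- params$rf == params$input_size
  f <- new.env(parent = emptyenv())
  f$params <- params
  f$W_aff <- if (params$freeze_afferent) {
    matrix(1, n, p)
  } else {
    normalize_rows(matrix(stats::runif(n * p), n, p))
  }
  f$W_exc <- normalize_rows(matrix(stats::runif(n * n), n, n) * masks$exc)
  f$W_inhb <- normalize_rows(matrix(stats::runif(n * n), n, n) * masks$inhb)
  f$mask_exc <- masks$exc
  f$mask_inhb <- masks$inhb
  f$eta <- numeric(n)
  f$eta_prev <- numeric(n)
  f$patch_idx <- if (shared_rf) NULL else patch_indices(params)
  f$shared_rf <- shared_rf
  class(f) <- "neural_field"
  f
}

# force an independent copy of a numeric object (weight matrices are
# updated in place by the C++ kernels, so plain assignment aliases)
copy_num <- function(m) m + 0

#' Deep-copy a neural field
#'
#' Fields are environments updated in place during training; `clone_field()`
#' returns an independent copy whose weights will not change when the
#' original trains further.
#'
#' @param field a `neural_field`.
#' @return an independent `neural_field`.
#' @export
clone_field <- function(field) {
  g <- new.env(parent = emptyenv())
  g$params <- field$params
  g$W_aff <- copy_num(field$W_aff)
  g$W_exc <- copy_num(field$W_exc)
  g$W_inhb <- copy_num(field$W_inhb)
  g$mask_exc <- field$mask_exc   # masks are never mutated
  g$mask_inhb <- field$mask_inhb
  g$eta <- copy_num(field$eta)
  g$eta_prev <- copy_num(field$eta_prev)
  g$patch_idx <- field$patch_idx
  g$shared_rf <- field$shared_rf
  class(g) <- "neural_field"
  g
}

#' @export
print.neural_field <- function(x, ...) {
  p <- x$params
  cat(sprintf(
    "<neural_field> %dx%d neurons, rf %dx%d on %dx%d input%s\n",
    p$dim, p$dim, p$rf, p$rf, p$input_size, p$input_size,
    if (p$freeze_afferent) " (afferents frozen)" else ""))
  cat(sprintf("  r_exc %.3g r_inhb %.3g | gains aff %.3g exc %.3g inhb %.3g | Ts %d\n",
              p$r_exc, p$r_inhb, p$gamma_aff, p$gamma_exc, p$gamma_inhb,
              p$settling_steps))
  invisible(x)
}

# extract RF patches for an input matrix -> n x rf^2 matrix
input_patches <- function(field, input) {
  matrix(input[field$patch_idx], nrow = field$params$dim^2)
}

check_input_geometry <- function(field, input) {
  if (!is.matrix(input) ||
      nrow(input) != field$params$input_size ||
      ncol(input) != field$params$input_size)
    abort(sprintf("input must be a %dx%d matrix, got %sx%s",
                  field$params$input_size, field$params$input_size,
                  nrow(input), ncol(input)))
}

#' Afferent response of a field
#'
#' Each neuron's feedforward drive: the scaled inner product of its
#' afferent weight patch with the input inside its receptive field, passed
#' through the piecewise-linear sigmoid.
#'
#' @param field a `neural_field`.
#' @param input input matrix matching the field's input sheet geometry.
#' @return numeric vector of length `dim^2` in \[0, 1\] (column-major over
#'   the sheet).
#' @export
afferent_response <- function(field, input) {
  check_input_geometry(field, input)
  p <- field$params
  lo <- p$sigma_aff_lo %||% p$sigma_lo
  hi <- p$sigma_aff_hi %||% p$sigma_hi
  if (field$shared_rf) {
    drive <- p$gamma_aff * as.vector(field$W_aff %*% as.vector(input))
    sigma_pl(drive, lo, hi)
  } else {
    X <- input_patches(field, input)
    as.vector(cpp_aff_response(field$W_aff, X, p$gamma_aff, lo, hi))
  }
}

#' Lateral settling dynamics
#'
#' Iterates the recurrent dynamics for `settling_steps` steps at a fixed
#' afferent drive `S`: at each step the neuron combines `S` with the
#' excitatory and inhibitory weighted sums of the previous step's activity
#' and squashes the result. The initially widespread response contracts
#' into a focused activity bubble.
#'
#' The iteration starts from `eta_init` — by default the field's current
#' activity, i.e. the settled response to the previous frame (zero right
#' after a reset). Activity is reset only *between* sequences, so within a
#' sequence the settled state carries across frames; this is what lets the
#' direction-adapted lateral circuitry shape the response to the next
#' frame, and with it distinguish a sequence from its time reversal.
#'
#' @param field a `neural_field`.
#' @param S afferent response vector from [afferent_response()].
#' @param eta_init starting activity for the iteration (default: the
#'   field's current settled activity).
#' @return settled activity vector in \[0, 1\].
#' @export
settle <- function(field, S, eta_init = NULL) {
  p <- field$params
  eta_init <- eta_init %||% field$eta
  as.vector(cpp_settle(S, eta_init, field$W_exc, field$W_inhb, p$gamma_exc,
                       p$gamma_inhb, p$settling_steps, p$sigma_lo,
                       p$sigma_hi))
}

#' Reset field activity
#'
#' Zeroes the current and previous settled-activity grids, as done between
#' stimulus sequences; after a reset no lateral learning can occur on the
#' first frame (the presynaptic factor of the asymmetric rule is zero).
#'
#' @param field a `neural_field`.
#' @return the field (modified in place), invisibly.
#' @export
reset_activity <- function(field) {
  n <- field$params$dim^2
  field$eta <- numeric(n)
  field$eta_prev <- numeric(n)
  invisible(field)
}

#' Serialize / restore a field
#'
#' Writes the weight tensors, activity grids and geometry to a single
#' `.rds` archive.
#'
#' @param field a `neural_field`.
#' @param path file path.
#' @return `save_field()` the path invisibly; `load_field()` the field.
#' @export
save_field <- function(field, path) {
  saveRDS(mget(ls(field, all.names = TRUE), envir = field), path)
  invisible(path)
}

#' @rdname save_field
#' @export
load_field <- function(path) {
  x <- readRDS(path)
  f <- list2env(x, parent = emptyenv())
  class(f) <- "neural_field"
  f
}
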