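#' Single-layer perceptron readout
#'
#' A multiclass perceptron with logistic output units, used as a probe of
#' how decodable the field's population response is; it is not part of the
#' modeled motion pathway. Weights and biases start at zero (so an
#' untrained model outputs 0.5 everywhere); all randomness is in the
#' per-epoch sample order during training.
#'
#' @param n_inputs input dimension (the source field's neuron count).
#' @param classes ordered class labels (e.g. direction angles).
#' @param alpha learning rate.
#' @return an object of class `perceptron`.
#' @export
new_perceptron <- function(n_inputs, classes, alpha = 0.1) {
  structure(
    list(W = matrix(0, length(classes), n_inputs),
         b = numeric(length(classes)),
         classes = classes, alpha = alpha, sse_trace = numeric(0)),
    class = "perceptron")
}

logistic <- function(x) 1 / (1 + exp(-x))

#' Perceptron forward pass
#'
#' Per-class outputs `O_i = g(sum_j W_ij I_j + b_i)` with `g` the logistic
#' sigmoid; the predicted class is the argmax.
#'
#' @param model a `perceptron`.
#' @param input numeric vector (a flattened settled-activity grid) or a
#'   samples-by-inputs matrix.
#' @return per-class outputs in (0, 1): a vector, or a samples-by-classes
#'   matrix for matrix input.
#' @export
perceptron_forward <- function(model, input) {
  if (is.matrix(input)) {
    if (ncol(input) != ncol(model$W)) abort("input dimension mismatch")
    out <- logistic(input %*% t(model$W) +
                      matrix(model$b, nrow(input), length(model$b),
                             byrow = TRUE))
    colnames(out) <- as.character(model$classes)
    out
  } else {
    if (length(input) != ncol(model$W)) abort("input dimension mismatch")
    as.vector(logistic(model$W %*% input + model$b))
  }
}

#' Train the perceptron by the delta rule
#'
#' Online (per-sample) updates in randomized order each epoch: for each
#' sample with one-hot target `y`, error `E = y - O`, `dW = alpha * E x I`,
#' `db = alpha * E` (per-class biases). The summed squared error per epoch
#' is recorded.
#'
#' @param model a `perceptron`.
#' @param features samples-by-inputs matrix.
#' @param labels class label per sample (must be in `model$classes`).
#' @param epochs number of passes over the training set.
#' @param alpha learning rate; default the model's.
#' @param seed seed for the per-epoch shuffles.
#' @return the trained `perceptron`; `$sse_trace` holds the per-epoch sum
#'   of squared errors.
#' @export
train_perceptron <- function(model, features, labels, epochs = 300,
                             alpha = NULL, seed = 1) {
  if (nrow(features) == 0) abort("empty training set")
  alpha <- alpha %||% model$alpha
  cls <- match(labels, model$classes)
  if (anyNA(cls)) abort("labels outside model classes")
  Y <- diag(length(model$classes))[cls, , drop = FALSE]  # one-hot rows
  W <- model$W; b <- model$b
  sse <- numeric(epochs)
  set.seed(seed)
  for (e in seq_len(epochs)) {
    err2 <- 0
    for (i in sample.int(nrow(features))) {
      x <- features[i, ]
      O <- as.vector(logistic(W %*% x + b))
      E <- Y[i, ] - O
      W <- W + alpha * tcrossprod(E, x)
      b <- b + alpha * E
      err2 <- err2 + sum(E^2)
    }
    sse[e] <- err2
  }
  model$W <- W
  model$b <- b
  model$sse_trace <- c(model$sse_trace, sse)
  model
}

#' Decoding accuracy
#'
#' Fraction of samples whose argmax class prediction matches the label.
#'
#' @param model a trained `perceptron`.
#' @param features samples-by-inputs matrix.
#' @param labels true class labels.
#' @return fraction correct in \[0, 1\].
#' @export
decode_accuracy <- function(model, features, labels) {
  O <- perceptron_forward(model, features)
  pred <- model$classes[max.col(O, ties.method = "first")]
  mean(pred == labels)
}

#' @export
print.perceptron <- function(x, ...) {
  cat(sprintf("<perceptron> %d classes x %d inputs, alpha %.3g, %d epoch(s) trained\n",
              nrow(x$W), ncol(x$W), x$alpha, length(x$sse_trace)))
  invisible(x)
}

#' Tidy / summarise a perceptron
#'
#' @param x a `perceptron`.
#' @param ... unused.
#' @return `tidy()`: the per-epoch error trace as a tibble (`epoch`,
#'   `sse`); `glance()`: one row with size and final error.
#' @export
tidy.perceptron <- function(x, ...) {
  tibble(epoch = seq_along(x$sse_trace), sse = x$sse_trace)
}

#' @rdname tidy.perceptron
#' @export
glance.perceptron <- function(x, ...) {
  tibble(n_classes = nrow(x$W), n_inputs = ncol(x$W),
         epochs_trained = length(x$sse_trace),
         final_sse = if (length(x$sse_trace))
           x$sse_trace[length(x$sse_trace)] else NA_real_)
}

#' Population feature vectors for decoding
#'
#' Extracts, per sequence, the flattened settled activity of a field as the
#' decoder's input: the final frame's activity by default (the flow
#' response is nearly stabilized across frames), or the mean over frames.
#'
#' @param network a trained `layered_network`.
#' @param sequences list of `stimulus_sequence`.
#' @param layer source field (default the top one).
#' @param frame `"final"` or `"mean"`.
#' @return samples-by-neurons matrix.
#' @export
nf_features <- function(network, sequences, layer = length(network$fields),
                        frame = c("final", "mean")) {
  frame <- match.arg(frame)
  t(vapply(sequences, function(s) {
    act <- present_sequence(network, s, upto = layer)$activity[[layer]]
    if (frame == "final") act[nrow(act), ] else colMeans(act)
  }, numeric(network$fields[[layer]]$params$dim^2)))
}
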