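# Naive loop implementations of the model equations, kept deliberately
# independent of the package's vectorized/C++ code paths. Used as oracles
# on small fields.

oracle_sigma <- function(x, lo = 0, hi = 1) {
  v <- (x - lo) / (hi - lo)
  ifelse(v <= 0, 0, ifelse(v >= 1, 1, v))
}

# afferent response: per-neuron double loop over its RF patch
oracle_afferent <- function(field, input) {
  p <- field$params
  lo <- if (is.null(p$sigma_aff_lo)) p$sigma_lo else p$sigma_aff_lo
  hi <- if (is.null(p$sigma_aff_hi)) p$sigma_hi else p$sigma_aff_hi
  n <- p$dim^2
  S <- numeric(n)
  for (i in seq_len(n)) {
    acc <- 0
    if (field$shared_rf) {
      acc <- sum(field$W_aff[i, ] * as.vector(input))
    } else {
      for (j in seq_len(p$rf^2))
        acc <- acc + field$W_aff[i, j] * input[field$patch_idx[i, j]]
    }
    S[i] <- oracle_sigma(p$gamma_aff * acc, lo, hi)
  }
  S
}

# settling: nested loops over steps and neuron pairs
oracle_settle <- function(field, S, eta0) {
  p <- field$params
  n <- p$dim^2
  eta <- eta0
  for (s in seq_len(p$settling_steps)) {
    nxt <- numeric(n)
    for (i in seq_len(n)) {
      exc <- 0; inhb <- 0
      for (k in seq_len(n)) {
        exc <- exc + field$W_exc[i, k] * eta[k]
        inhb <- inhb + field$W_inhb[i, k] * eta[k]
      }
      nxt[i] <- oracle_sigma(S[i] + p$gamma_exc * exc - p$gamma_inhb * inhb,
                             p$sigma_lo, p$sigma_hi)
    }
    eta <- nxt
  }
  eta
}

# one full frame update (afferent + both lateral types + divisive
# normalization per type), computed entry by entry
oracle_frame_update <- function(field, rule, input, eta_t) {
  p <- field$params
  n <- p$dim^2
  W_aff <- field$W_aff
  if (!rule$freeze_afferent && !p$freeze_afferent) {
    for (i in seq_len(n)) {
      x <- if (field$shared_rf) as.vector(input) else
        input[field$patch_idx[i, ]]
      w <- W_aff[i, ] + p$alpha_aff * x * eta_t[i]
      if (sum(w) > 0) w <- w / sum(w)
      W_aff[i, ] <- w
    }
  }
  if (rule$mode == "asymmetric") {
    post <- pmax(0, eta_t - field$eta_prev); pre <- field$eta_prev
  } else {
    post <- eta_t; pre <- eta_t
  }
  upd_lat <- function(W, mask, alpha) {
    for (i in seq_len(n)) {
      w <- W[i, ]
      for (k in seq_len(n))
        if (mask[i, k] > 0) w[k] <- w[k] + alpha * post[i] * pre[k]
      if (sum(w) > 0) w <- w / sum(w)
      W[i, ] <- w
    }
    W
  }
  list(W_aff = W_aff,
       W_exc = upd_lat(field$W_exc, field$mask_exc, p$alpha_exc),
       W_inhb = upd_lat(field$W_inhb, field$mask_inhb, p$alpha_inhb))
}

# perceptron forward + one online training epoch, elementwise
oracle_perceptron_epoch <- function(W, b, X, Y, alpha, order) {
  for (i in order) {
    O <- numeric(nrow(W))
    for (c in seq_len(nrow(W))) {
      z <- b[c]
      for (j in seq_len(ncol(W))) z <- z + W[c, j] * X[i, j]
      O[c] <- 1 / (1 + exp(-z))
    }
    for (c in seq_len(nrow(W))) {
      E <- Y[i, c] - O[c]
      for (j in seq_len(ncol(W))) W[c, j] <- W[c, j] + alpha * X[i, j] * E
      b[c] <- b[c] + alpha * E
    }
  }
  list(W = W, b = b)
}

# small random field for oracle comparisons
tiny_field <- function(dim = 4, rf = 3, input_size = 6, seed = 42,
                       gamma_exc = 1.5, gamma_inhb = 1, settling_steps = 3,
                       sigma_hi = 1, freeze_afferent = FALSE) {
  fp <- field_params(dim = dim, rf = rf, input_size = input_size,
                     r_exc = 1.5, r_inhb = 3, gamma_exc = gamma_exc,
                     gamma_inhb = gamma_inhb,
                     settling_steps = settling_steps,
                     sigma_hi = sigma_hi, freeze_afferent = freeze_afferent)
  new_field(fp, seed = seed)
}

rand_input <- function(size, seed) {
  set.seed(seed)
  matrix(runif(size * size), size, size)
}
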