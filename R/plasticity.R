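#' Learning rule
#'
#' Selects the lateral plasticity variant and the per-type learning rates.
#' `"asymmetric"` is the model's temporally asymmetric Hebbian rule (the
#' rate-based analogue of STDP); `"symmetric"` is the classical Hebbian
#' control used to show that temporal asymmetry, not lateral plasticity per
#' se, produces direction selectivity.
#'
#' @param mode `"asymmetric"` or `"symmetric"`.
#' @param alpha_aff,alpha_exc,alpha_inhb learning rates; `NULL` means use
#'   the field's own rates.
#' @param freeze_afferent if `TRUE`, afferent weights are never updated.
#' @return an object of class `learning_rule`.
#' @export
learning_rule <- function(mode = c("asymmetric", "symmetric"),
                          alpha_aff = NULL, alpha_exc = NULL,
                          alpha_inhb = NULL, freeze_afferent = FALSE) {
  mode <- match.arg(mode)
  structure(list(mode = mode, alpha_aff = alpha_aff, alpha_exc = alpha_exc,
                 alpha_inhb = alpha_inhb, freeze_afferent = freeze_afferent),
            class = "learning_rule")
}

#' Hebbian weight increments
#'
#' The elementary weight-increment rules, exposed for inspection and
#' testing; training applies them through [apply_frame_update()].
#'
#' `afferent_delta()`: increment of an afferent weight, learning rate times
#' input pixel times the neuron's settled activity for the current frame.
#'
#' `lateral_delta_asymmetric()`: increment of a lateral weight from
#' presynaptic neuron activity at the *previous* frame times the rectified
#' *increase* in postsynaptic activity at the current frame; zero whenever
#' postsynaptic activity is non-increasing, and zero on the first frame
#' after a reset.
#'
#' `lateral_delta_symmetric()`: the temporally symmetric control, product
#' of both neurons' activities at the current frame.
#'
#' @param input_patch,eta_ij input value(s) and postsynaptic settled
#'   activity for the current frame.
#' @param eta_post_t,eta_post_tm1 postsynaptic settled activity at the
#'   current / previous frame.
#' @param eta_pre_tm1,eta_pre_t presynaptic settled activity at the
#'   previous / current frame.
#' @param alpha,alpha_aff learning rate.
#' @return weight increment(s), always non-negative for activities and
#'   inputs in \[0, 1\].
#' @name hebbian_deltas
NULL

#' @rdname hebbian_deltas
#' @export
afferent_delta <- function(input_patch, eta_ij, alpha_aff) {
  alpha_aff * input_patch * eta_ij
}

#' @rdname hebbian_deltas
#' @export
lateral_delta_asymmetric <- function(eta_post_t, eta_post_tm1, eta_pre_tm1,
                                     alpha) {
  alpha * pmax(0, eta_post_t - eta_post_tm1) * eta_pre_tm1
}

#' @rdname hebbian_deltas
#' @export
lateral_delta_symmetric <- function(eta_post_t, eta_pre_t, alpha) {
  alpha * eta_post_t * eta_pre_t
}

#' Postsynaptic divisive normalization
#'
#' Rescales one neuron's incoming weights of one connection type after an
#' update so they sum to 1: `(W + dW) / sum(W + dW)`. Afferent, excitatory
#' and inhibitory weights are each normalized separately. A zero
#' denominator (a dead neuron with no incoming weight) leaves the weights
#' unchanged with a warning.
#'
#' @param weights_in incoming weights of one type for one neuron.
#' @param deltas_in the corresponding increments.
#' @return normalized weights summing to 1.
#' @export
divisive_normalize <- function(weights_in, deltas_in = 0) {
  w <- weights_in + deltas_in
  s <- sum(w)
  if (s <= 0) {
    warn("all-zero incoming weights; divisive normalization skipped")
    return(weights_in)
  }
  w / s
}

#' Per-frame weight update
#'
#' Applies, after the activity has settled on a frame, the afferent Hebbian
#' update (unless frozen) and the lateral excitatory and inhibitory updates
#' under the chosen rule, each followed by per-neuron divisive
#' normalization of that connection type, then records the settled activity
#' as the previous-frame activity for the next update.
#'
#' @param field a `neural_field` (updated in place).
#' @param rule a [learning_rule()].
#' @param input the input matrix the frame's afferent response was computed
#'   from.
#' @param eta_t the settled activity for the current frame.
#' @return the updated field, invisibly.
#' @export
apply_frame_update <- function(field, rule, input, eta_t) {
  p <- field$params
  a_aff <- rule$alpha_aff %||% p$alpha_aff
  a_exc <- rule$alpha_exc %||% p$alpha_exc
  a_inhb <- rule$alpha_inhb %||% p$alpha_inhb
  if (!rule$freeze_afferent && !p$freeze_afferent) {
    if (field$shared_rf) {
      cpp_update_aff_shared(field$W_aff, as.vector(input), eta_t, a_aff)
    } else {
      cpp_update_aff(field$W_aff, input_patches(field, input), eta_t, a_aff)
    }
  }
  if (rule$mode == "asymmetric") {
    post <- pmax(0, eta_t - field$eta_prev)
    pre <- field$eta_prev
  } else {
    post <- eta_t
    pre <- eta_t
  }
  cpp_update_lat(field$W_exc, post, pre, a_exc, field$mask_exc)
  cpp_update_lat(field$W_inhb, post, pre, a_inhb, field$mask_inhb)
  field$eta_prev <- eta_t
  field$eta <- eta_t
  invisible(field)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
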