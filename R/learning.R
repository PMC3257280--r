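#' Learning-rule settings
#'
#' @param learning_rate learning rate eta (> 0); 0.2 is the default
#'   operating point.
#' @param rate_scaling `"times_n"` multiplies the gradient by N (so the
#'   per-neuron and per-output trial-to-trial variation does not depend on
#'   N explicitly); `"optimal"` instead uses the closed-form optimal rate
#'   `2 / (lambda_min + lambda_max)` of the decoder's learning operator.
#'   For `1/sqrt(N)`-scaled high-dimensional decoders the N factor is
#'   already absorbed by the scaling and is not applied.
#' @param decay synaptic decay rate lambda in `[0, 1)`; positive decay
#'   pulls weights toward zero every trial and creates a residual error
#'   floor.
#' @param drift_sd strength of synaptic drift: i.i.d. Gaussian noise added
#'   to every weight after the decay and gradient terms.
#' @param decoder_rate learning rate of the adaptable decoder (0 = fixed
#'   decoder); 0.1 and 0.05 are the two operating points used in the
#'   adaptable-decoder and high-dimensional-task protocols.
#' @param rule `"gradient"`, `"weight_perturbation"` or
#'   `"node_perturbation"`.
#' @param perturbation_sd standard deviation sigma_p of the stochastic
#'   rules' probe perturbations (> 0 for those rules).
#' @return an object of class `"learning_spec"`.
#' @export
learning_spec <- function(learning_rate = 0.2,
                          rate_scaling = c("times_n", "optimal"),
                          decay = 0, drift_sd = 0, decoder_rate = 0,
                          rule = c("gradient", "weight_perturbation",
                                   "node_perturbation"),
                          perturbation_sd = 0.01) {
  check_scalar(learning_rate, "learning_rate", positive = TRUE)
  check_scalar(decay, "decay", nonnegative = TRUE)
  if (decay >= 1) stop_invalid("`decay` must be in [0, 1)")
  check_scalar(drift_sd, "drift_sd", nonnegative = TRUE)
  check_scalar(decoder_rate, "decoder_rate", nonnegative = TRUE)
  rule <- match.arg(rule)
  check_scalar(perturbation_sd, "perturbation_sd", nonnegative = TRUE)
  if (rule != "gradient" && perturbation_sd <= 0) {
    stop_invalid("stochastic rules require `perturbation_sd` > 0")
  }
  structure(list(learning_rate = learning_rate,
                 rate_scaling = match.arg(rate_scaling),
                 decay = decay, drift_sd = drift_sd,
                 decoder_rate = decoder_rate, rule = rule,
                 perturbation_sd = perturbation_sd),
            class = "learning_spec")
}

# Gradient premultiplier: N for 1/N-scaled decoders (the explicit N of the
# update rule), 1 for 1/sqrt(N)-scaled high-dimensional decoders.
grad_scale <- function(state) {
  if (state$decoder$scaling == "inv_n") state$decoder$n_neurons else 1
}

effective_rate <- function(spec, state) {
  if (spec$rate_scaling == "optimal") {
    ev <- eigen(build_A(state$decoder), symmetric = TRUE,
                only.values = TRUE)$values
    optimal_learning_rate(ev)
  } else {
    spec$learning_rate
  }
}

# d(-E)/d(preactivation): the N-vector whose outer product with the input
# is the (negative) weight gradient. Chains through muscle readout,
# saturating activation and the recurrent fixed point as needed.
backward_delta_pre <- function(state, fwd) {
  back <- drop(t(rotation_matrix(fwd$phi)) %*% fwd$error_vector)
  if (!is.null(state$muscle)) {
    pd <- state$muscle$pull_dirs
    drive_grad <- (cos(pd) * back[1L] + sin(pd) * back[2L]) *
      (fwd$drives > 0)
    delta_u <- drop(crossprod(state$muscle$matrix, drive_grad))
  } else {
    delta_u <- drop(crossprod(state$decoder$matrix, back))
  }
  if (!is.null(state$recurrent)) {
    solve(t(diag(nrow(state$weights)) - state$recurrent), delta_u)
  } else if (state$activation == "saturating") {
    (1 - fwd$activities_det^2) * delta_u
  } else {
    delta_u
  }
}

apply_decay_drift <- function(W, spec) {
  W <- (1 - spec$decay) * W
  if (spec$drift_sd > 0) {
    W <- W + matrix(rnorm(length(W), sd = spec$drift_sd), nrow(W), ncol(W))
  }
  W
}

#' Gradient-descent weight update
#'
#' One trial of the core update rule: with decay lambda, learning rate eta
#' and drift sigma_w,
#' `W <- (1 - lambda) W + scale * eta * D^T R(phi)^T (y* - y) x^T + sigma_w * Xi`,
#' where `scale` is N for `1/N`-scaled decoders (chain rule replaces the
#' middle term for the saturating, recurrent and muscle variants). With
#' zero error, decay and drift, the weights are a fixed point.
#'
#' @param state a [network_state()].
#' @param fwd the [forward()] result produced from `state` on this trial.
#' @param input the encoded input of this trial.
#' @param phi the rotation applied on this trial.
#' @param spec a [learning_spec()].
#' @param noise a [noise_spec()] (drift is read from `spec`; `noise` is
#'   accepted for interface symmetry with the decoder update).
#' @return the updated `"network_state"` (trial index advanced).
#' @export
gradient_step <- function(state, fwd, input, phi, spec,
                          noise = noise_spec()) {
  stopifnot(inherits(state, "network_state"),
            inherits(fwd, "forward_result"),
            inherits(spec, "learning_spec"))
  input <- as.numeric(input)
  if (length(input) != ncol(state$weights)) {
    stop_invalid("input length does not match weight columns")
  }
  delta_pre <- backward_delta_pre(state, fwd)
  eta <- effective_rate(spec, state)
  dW <- grad_scale(state) * eta * tcrossprod(delta_pre, input)
  state$weights <- apply_decay_drift(state$weights, spec) + dW
  state$trial_index <- state$trial_index + 1L
  log_step("gradient", state$trial_index, fwd$squared_error,
           sqrt(sum(dW^2)))
  state
}

#' Adaptable-decoder update
#'
#' Error-driven decoder plasticity (the backpropagation counterpart of the
#' weight rule): `D <- D + eta_D * R(phi)^T (y* - y) u^T / N`, plus
#' Gaussian plasticity noise scaled by `eta_D`. Apply in the same trial as
#' [gradient_step()], which must use the pre-update decoder (call
#' `gradient_step` first; it only touches the weights).
#'
#' @param state a [network_state()] with `adaptable_decoder = TRUE`.
#' @param fwd the [forward()] result of this trial (supplies u, the error
#'   and the rotation).
#' @param spec a [learning_spec()] with `decoder_rate` > 0.
#' @param noise a [noise_spec()]; `decoder_plasticity_sd` scales the
#'   decoder noise.
#' @return the updated `"network_state"`.
#' @export
decoder_step <- function(state, fwd, spec, noise = noise_spec()) {
  stopifnot(inherits(state, "network_state"),
            inherits(fwd, "forward_result"),
            inherits(spec, "learning_spec"))
  if (!state$adaptable_decoder) {
    stop_invalid("decoder_step() called on a fixed-decoder state")
  }
  dec <- state$decoder
  back <- drop(t(rotation_matrix(fwd$phi)) %*% fwd$error_vector)
  dD <- spec$decoder_rate * tcrossprod(back, fwd$activities) / dec$n_neurons
  if (noise$decoder_plasticity_sd > 0) {
    dD <- dD + spec$decoder_rate *
      matrix(rnorm(length(dD), sd = noise$decoder_plasticity_sd),
             nrow(dD), ncol(dD))
  }
  dec$matrix <- dec$matrix + dD
  dec$raw <- dec$matrix *
    if (dec$scaling == "inv_n") dec$n_neurons else sqrt(dec$n_neurons)
  state$decoder <- dec
  log_step("decoder", state$trial_index, fwd$squared_error,
           sqrt(sum(dD^2)))
  state
}

#' Weight-perturbation update (stochastic gradient)
#'
#' Probes the error landscape with a Gaussian weight perturbation Psi
#' (sd `perturbation_sd`) and moves against the measured error change:
#' `W <- (1 - lambda) W - scale * eta * ((E+ - E) / sigma_p^2) * Psi + drift`,
#' where `E+ = E(W + Psi)` (both errors evaluated noise-free). In
#' expectation this is the gradient update; for small sigma_p the
#' estimator variance stays bounded.
#'
#' @param state a [network_state()].
#' @param input,target,phi the trial context.
#' @param spec a [learning_spec()] with `rule = "weight_perturbation"`.
#' @param noise a [noise_spec()].
#' @return the updated `"network_state"`.
#' @export
weight_perturbation_step <- function(state, input, target, phi, spec,
                                     noise = noise_spec()) {
  stopifnot(inherits(state, "network_state"), inherits(spec, "learning_spec"))
  if (spec$perturbation_sd <= 0) stop_invalid("`perturbation_sd` must be > 0")
  quiet <- noise_spec()
  e0 <- forward(state, input, target, phi, quiet)$squared_error
  Psi <- matrix(rnorm(length(state$weights), sd = spec$perturbation_sd),
                nrow(state$weights), ncol(state$weights))
  pert <- state
  pert$weights <- state$weights + Psi
  e1 <- forward(pert, input, target, phi, quiet)$squared_error
  gamma <- (e1 - e0) / spec$perturbation_sd^2
  eta <- effective_rate(spec, state)
  dW <- -grad_scale(state) * eta * gamma * Psi
  state$weights <- apply_decay_drift(state$weights, spec) + dW
  state$trial_index <- state$trial_index + 1L
  log_step("weight_perturbation", state$trial_index, e0, sqrt(sum(dW^2)))
  state
}

#' Node-perturbation update (stochastic gradient)
#'
#' Probes with a Gaussian perturbation of the activities instead of the
#' weights: `W <- (1 - lambda) W - scale * eta * ((E+ - E) / sigma_p^2) * psi x^T + drift`,
#' where `E+` is the error after perturbing u by psi. The estimator
#' dimension is N rather than N x input-dim, giving a lower-variance
#' per-trial gradient estimate than weight perturbation.
#'
#' @inheritParams weight_perturbation_step
#' @return the updated `"network_state"`.
#' @export
node_perturbation_step <- function(state, input, target, phi, spec,
                                   noise = noise_spec()) {
  stopifnot(inherits(state, "network_state"), inherits(spec, "learning_spec"))
  if (spec$perturbation_sd <= 0) stop_invalid("`perturbation_sd` must be > 0")
  quiet <- noise_spec()
  fwd0 <- forward(state, input, target, phi, quiet)
  psi <- rnorm(nrow(state$weights), sd = spec$perturbation_sd)
  u_pert <- fwd0$activities_det + psi
  if (!is.null(state$muscle)) {
    force <- rectified_muscle_readout(u_pert, state$muscle$matrix,
                                      state$muscle$pull_dirs)
  } else {
    force <- drop(state$decoder$matrix %*% u_pert)
  }
  hand <- if (length(force) == 2L) drop(rotation_matrix(phi) %*% force)
          else force
  e1 <- 0.5 * sum((as.numeric(target) - hand)^2)
  gamma <- (e1 - fwd0$squared_error) / spec$perturbation_sd^2
  eta <- effective_rate(spec, state)
  dW <- -grad_scale(state) * eta * gamma * tcrossprod(psi, as.numeric(input))
  state$weights <- apply_decay_drift(state$weights, spec) + dW
  state$trial_index <- state$trial_index + 1L
  log_step("node_perturbation", state$trial_index, fwd0$squared_error,
           sqrt(sum(dW^2)))
  state
}
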