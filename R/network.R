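#' Trial-to-trial noise settings
#'
#' @param activity_sd standard deviation of the additive Gaussian noise on
#'   neural activities (applied after the activation nonlinearity).
#' @param plasticity_sd standard deviation of the synaptic drift added to
#'   every weight on every update.
#' @param decoder_plasticity_sd standard deviation of the noise on
#'   adaptable-decoder updates (scaled by the decoder learning rate).
#' @return an object of class `"noise_spec"`.
#' @export
noise_spec <- function(activity_sd = 0, plasticity_sd = 0,
                       decoder_plasticity_sd = 0) {
  check_scalar(activity_sd, "activity_sd", nonnegative = TRUE)
  check_scalar(plasticity_sd, "plasticity_sd", nonnegative = TRUE)
  check_scalar(decoder_plasticity_sd, "decoder_plasticity_sd",
               nonnegative = TRUE)
  structure(list(activity_sd = activity_sd, plasticity_sd = plasticity_sd,
                 decoder_plasticity_sd = decoder_plasticity_sd),
            class = "noise_spec")
}

#' Build a muscle set for the rectified (pull-only) readout
#'
#' `n_muscles` muscles in antagonist pairs with equally spaced pull
#' directions; each neuron drives the muscles through a random drive
#' matrix with `1/N` scaling (adapted jointly with the weights through the
#' chain rule). A muscle contributes force `max(0, drive) * pull_dir`:
#' muscles can pull but cannot push.
#'
#' @param n_neurons number of neurons N.
#' @param n_muscles even number of muscles (default 8, four antagonist
#'   pairs).
#' @param tone baseline drive added to every muscle. With equally spaced
#'   pull directions the tonic contributions cancel (zero net force at
#'   rest) but keep all rectifiers in their active region, so learning
#'   can start from zero weights.
#' @param seed optional RNG seed.
#' @return list with `matrix` (n_muscles x N drive matrix), `pull_dirs`
#'   and `tone`.
#' @export
make_muscle_set <- function(n_neurons, n_muscles = 8L, tone = 1,
                            seed = NULL) {
  check_scalar(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  check_scalar(n_muscles, "n_muscles", positive = TRUE, integerish = TRUE)
  check_scalar(tone, "tone", nonnegative = TRUE)
  P <- as.integer(n_muscles)
  mat <- with_seed(seed, matrix(rnorm(P * n_neurons), P, n_neurons)) / n_neurons
  list(matrix = mat, pull_dirs = 2 * pi * (seq_len(P) - 1L) / P,
       tone = tone)
}

#' Network state
#'
#' The mutable learner: input weights `W` (N x input dimension, zero at
#' initialization -- baseline trials then reach the unperturbed solution),
#' a decoder sample, and optional structural variants (saturating
#' activation, fixed recurrent connections, rectified muscle readout,
#' adaptable decoder).
#'
#' @param decoder a [decoder_sample()].
#' @param input_dim input dimensionality (2 for cosine encoding, the
#'   number of von Mises units, or the task count for high-dimensional
#'   task sets).
#' @param activation `"linear"` or `"saturating"` (odd sigmoid `tanh`,
#'   slope 1 at the origin).
#' @param recurrent optional N x N recurrent weight matrix; activities are
#'   the exact linear fixed point `u = W x + K u`, which requires spectral
#'   radius < 1. Only supported with linear activation.
#' @param muscle optional muscle set from [make_muscle_set()]; replaces
#'   the linear decoder readout by the rectified muscle readout.
#' @param adaptable_decoder logical; must be `TRUE` for [decoder_step()]
#'   to be applicable.
#' @return an object of class `"network_state"`.
#' @export
network_state <- function(decoder, input_dim = 2L,
                          activation = c("linear", "saturating"),
                          recurrent = NULL, muscle = NULL,
                          adaptable_decoder = FALSE) {
  stopifnot(inherits(decoder, "decoder_sample"))
  check_scalar(input_dim, "input_dim", positive = TRUE, integerish = TRUE)
  activation <- match.arg(activation)
  N <- decoder$n_neurons
  if (!is.null(recurrent)) {
    if (!is.matrix(recurrent) || any(dim(recurrent) != N)) {
      stop_invalid("`recurrent` must be an N x N matrix")
    }
    if (spectral_radius(recurrent) >= 1) {
      stop_invalid("recurrent spectral radius >= 1: fixed point unstable")
    }
    if (activation != "linear") {
      stop_invalid("recurrent connections are only supported with linear activation")
    }
  }
  if (!is.null(muscle)) {
    stopifnot(is.list(muscle), is.matrix(muscle$matrix),
              ncol(muscle$matrix) == N,
              length(muscle$pull_dirs) == nrow(muscle$matrix))
  }
  structure(list(weights = matrix(0, N, as.integer(input_dim)),
                 decoder = decoder, recurrent = recurrent,
                 activation = activation, muscle = muscle,
                 adaptable_decoder = isTRUE(adaptable_decoder),
                 trial_index = 0L),
            class = "network_state")
}

#' @export
print.network_state <- function(x, ...) {
  cat(sprintf(
    "Network state: %d neurons, input dim %d, %s activation%s%s%s, trial %d\n",
    nrow(x$weights), ncol(x$weights), x$activation,
    if (!is.null(x$recurrent)) ", recurrent" else "",
    if (!is.null(x$muscle)) ", rectified muscles" else "",
    if (x$adaptable_decoder) ", adaptable decoder" else "",
    x$trial_index))
  invisible(x)
}

#' Saturating activation
#'
#' Elementwise odd sigmoid (hyperbolic tangent): values in `(-1, 1)`,
#' slope 1 at the origin so the small-signal regime matches the linear
#' network.
#'
#' @param z numeric vector.
#' @return numeric vector of the same length.
#' @export
saturating_activation <- function(z) {
  if (any(!is.finite(z))) stop_invalid("non-finite activation input")
  tanh(z)
}

#' Rectified (pull-only) muscle readout
#'
#' Each muscle's activation is the non-negative part of its commanded
#' drive; the output force is the pull-direction-weighted sum
#' `sum_j max(0, drive_j) * (cos pd_j, sin pd_j)`.
#'
#' @param activities N-vector of neural activities.
#' @param drive_matrix n_muscles x N matrix mapping activities to drives.
#' @param pull_dirs muscle pull directions (radians), non-empty.
#' @return 2-vector of output force.
#' @export
rectified_muscle_readout <- function(activities, drive_matrix, pull_dirs) {
  if (length(pull_dirs) == 0L) stop_invalid("`pull_dirs` must be non-empty")
  drives <- drop(drive_matrix %*% activities)
  act <- pmax(drives, 0)
  c(sum(act * cos(pull_dirs)), sum(act * sin(pull_dirs)))
}

#' Forward pass: activities, force, hand coordinate and error
#'
#' Computes `u = act(W x (+ K u))` plus activity noise, `f = D u` (or the
#' rectified muscle readout), `y = R(phi) f`, and the squared error
#' `E = (1/2) * ||y* - y||^2`. Deterministic when `activity_sd = 0`.
#'
#' @param state a [network_state()].
#' @param input encoded input vector (length = input dim of the state).
#' @param target target vector y* (length = output dim).
#' @param phi rotation perturbation in radians (0 during baseline).
#' @param noise a [noise_spec()].
#' @return an object of class `"forward_result"`: list with `activities`
#'   (noisy u), `activities_det` (noise-free, used by the backward pass),
#'   `preactivation`, `force`, `hand`, `error_vector`, `squared_error`,
#'   `drives` (muscle variant only) and `phi`.
#' @export
forward <- function(state, input, target, phi = 0, noise = noise_spec()) {
  stopifnot(inherits(state, "network_state"))
  input <- as.numeric(input)
  if (length(input) != ncol(state$weights)) {
    stop_invalid("input length %d does not match input dim %d",
                 length(input), ncol(state$weights))
  }
  pre <- drop(state$weights %*% input)
  if (!is.null(state$recurrent)) {
    # exact linear fixed point u = W x + K u
    u_det <- solve(diag(nrow(state$weights)) - state$recurrent, pre)
  } else if (state$activation == "saturating") {
    u_det <- saturating_activation(pre)
  } else {
    u_det <- pre
  }
  u <- u_det
  if (noise$activity_sd > 0) {
    u <- u + rnorm(length(u), sd = noise$activity_sd)
  }
  drives <- NULL
  if (!is.null(state$muscle)) {
    tone <- if (is.null(state$muscle$tone)) 0 else state$muscle$tone
    drives <- drop(state$muscle$matrix %*% u) + tone
    force <- c(sum(pmax(drives, 0) * cos(state$muscle$pull_dirs)),
               sum(pmax(drives, 0) * sin(state$muscle$pull_dirs)))
  } else {
    force <- drop(state$decoder$matrix %*% u)
  }
  target <- as.numeric(target)
  if (length(target) != length(force)) {
    stop_invalid("target length %d does not match output dim %d",
                 length(target), length(force))
  }
  hand <- if (length(force) == 2L) {
    drop(rotation_matrix(phi) %*% force)
  } else {
    force  # rotations are defined for planar outputs only
  }
  err <- target - hand
  structure(list(activities = u, activities_det = u_det,
                 preactivation = pre, force = force, hand = hand,
                 error_vector = err, squared_error = 0.5 * sum(err^2),
                 drives = drives, phi = phi),
            class = "forward_result")
}
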