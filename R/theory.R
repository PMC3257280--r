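#' Analytic learning curve of the noise-free single-target dynamics
#'
#' With a fixed decoder, no decay/noise and a single repeated target, the
#' error vector contracts per trial as `e <- (I - eta * A) e`, so in A's
#' eigenbasis `E_t = (1/2) * sum_k (1 - eta * lambda_k)^(2t) * e0_k^2`.
#' When a rotation is applied, pass the rotated operator
#' `R A R^T` (same spectrum) as `A`.
#'
#' @param A the symmetric learning operator acting on the error (M x M).
#' @param eta learning rate.
#' @param initial_error_vector error vector at trial 0.
#' @param n_trials number of trials to return.
#' @return numeric vector `E_t` for t = 0..n_trials-1 (so the first entry
#'   is the initial squared error).
#' @export
#' @examples
#' A <- diag(2) / 2
#' analytic_curve(A, 0.2, c(1, 0), 3)  # 0.5 * 0.81^t
analytic_curve <- function(A, eta, initial_error_vector, n_trials) {
  check_scalar(eta, "eta", nonnegative = TRUE)
  check_scalar(n_trials, "n_trials", positive = TRUE, integerish = TRUE)
  es <- if (is.matrix(A) && all(dim(A) == 2L)) eigensystem_2x2(A)
        else eigen((A + t(A)) / 2, symmetric = TRUE)
  e0 <- drop(crossprod(es$vectors, as.numeric(initial_error_vector)))
  rho2 <- (1 - eta * es$values)^2
  tt <- seq_len(n_trials) - 1L
  0.5 * colSums(outer(rho2, tt, `^`) * e0^2)
}

#' Smallest eigen-speed of a decoder and its attainment
#'
#' Learning speed is governed by the smaller eigenvalue of the learning
#' operator. For unit-norm force vectors `trace(A) = 1`, so
#' `lambda_min <= 1/2`, with equality iff the empirical second moments are
#' isotropic -- the self-averaging condition that sufficient neuronal
#' redundancy (N >> 1) delivers.
#'
#' @param dec a [decoder_sample()] with 2 outputs.
#' @param tol attainment tolerance on `|lambda_min - trace/2|`.
#' @return list with `lambda_min` and `is_maximal`.
#' @export
learning_speed_bound <- function(dec, tol = 1e-6) {
  stopifnot(inherits(dec, "decoder_sample"))
  if (dec$n_outputs != 2L) stop_invalid("requires a 2-output decoder")
  A <- build_A(dec)
  ev <- eigensystem_2x2(A)$values
  list(lambda_min = ev[2L],
       is_maximal = abs(ev[2L] - sum(diag(A)) / 2) < tol)
}

#' Optimal learning rate for a spectrum
#'
#' The rate minimizing the worst per-mode contraction
#' `max_k (1 - eta * lambda_k)^2` over the positive modes:
#' `eta* = 2 / (lambda_min+ + lambda_max)` (equivalently `1 / lambda` for
#' a single positive mode). Zero modes carry no error dynamics and are
#' excluded.
#'
#' @param eigenvalues numeric vector of operator eigenvalues.
#' @param tol eigenvalues below `tol` are treated as zero.
#' @return the optimal rate (positive scalar).
#' @export
optimal_learning_rate <- function(eigenvalues, tol = 1e-12) {
  if (!is.numeric(eigenvalues) || length(eigenvalues) == 0L) {
    stop_invalid("`eigenvalues` must be a non-empty numeric vector")
  }
  pos <- eigenvalues[eigenvalues > tol]
  if (length(pos) == 0L) {
    stop_invalid("all eigenvalues are zero: no learning is possible")
  }
  2 / (min(pos) + max(pos))
}

#' Asymptotic residual error under synaptic decay and drift
#'
#' With decay `lambda_d > 0` the weights are pulled toward zero every
#' trial, so the error no longer converges to zero: per eigenmode the mean
#' command settles at `eta * lambda_k / (lambda_d + eta * lambda_k)` of
#' the target and drift adds a stationary variance
#' `sigma_w^2 lambda_k / N / (1 - a_k^2)` with
#' `a_k = 1 - lambda_d - eta * lambda_k`. The residual squared error is
#' averaged over the targets passed in `targets` (a matrix of columns); by
#' symmetry, averaging over equally spaced targets makes the residual a
#' function of the spectrum alone, decreasing in `lambda_min`.
#'
#' @param A learning operator (M x M symmetric).
#' @param eta learning rate.
#' @param decay synaptic decay rate in `[0, 1)`.
#' @param drift_sd synaptic drift strength sigma_w.
#' @param targets target vector (length M) or matrix with one target per
#'   column; the returned residual is the mean over columns.
#' @param n_neurons N (sets the drift contribution; drift noise reaches
#'   the command through the decoder, attenuated by 1/N).
#' @return non-negative scalar: the asymptotic mean squared error.
#' @export
residual_error_with_decay <- function(A, eta, decay, drift_sd, targets,
                                      n_neurons) {
  check_scalar(eta, "eta", positive = TRUE)
  check_scalar(decay, "decay", nonnegative = TRUE)
  check_scalar(drift_sd, "drift_sd", nonnegative = TRUE)
  check_scalar(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  es <- if (is.matrix(A) && all(dim(A) == 2L)) eigensystem_2x2(A)
        else eigen((A + t(A)) / 2, symmetric = TRUE)
  a <- 1 - decay - eta * es$values
  if (any(abs(a) >= 1)) {
    stop_invalid("unstable configuration: |1 - decay - eta*lambda| >= 1")
  }
  targets <- if (is.matrix(targets)) targets else matrix(targets, ncol = 1L)
  y_tilde <- crossprod(es$vectors, targets)      # modes x targets
  mean_err2 <- (decay / (decay + eta * es$values))^2 * rowMeans(y_tilde^2)
  drift_var <- if (drift_sd > 0) {
    drift_sd^2 * es$values / n_neurons / (1 - a^2)
  } else {
    rep(0, length(a))
  }
  0.5 * sum(mean_err2 + drift_var)
}

#' Predicted motor-command change at a probe direction
#'
#' A single gradient update at the trained direction changes the motor
#' command at any probe direction by
#' `eta * g(theta_trained - theta_probe) * R A R^T * (y* - y)`: the
#' generalization function g scales how the correction transfers across
#' directions. Exact for the linear fixed-decoder model.
#'
#' @param A learning operator.
#' @param enc an [input_encoding()].
#' @param theta_trained,theta_probe trained and probe directions
#'   (radians).
#' @param eta learning rate.
#' @param error_vector the error observed at the trained direction.
#' @param phi rotation perturbation.
#' @return 2-vector: predicted change of the hand coordinate at the probe
#'   direction.
#' @export
command_update_prediction <- function(A, enc, theta_trained, theta_probe,
                                      eta, error_vector, phi) {
  g <- sum(encode_direction(theta_trained, enc) *
             encode_direction(theta_probe, enc))
  R <- rotation_matrix(phi)
  drop(eta * g * R %*% A %*% t(R) %*% as.numeric(error_vector))
}

#' Multi-target error/update alignment check
#'
#' Under a rotational perturbation the errors at any two targets have
#' inner product proportional to the cosine of the target separation --
#' the same profile by which cosine-encoded updates transfer. The
#' recursion argument for multi-target learning therefore needs the cross
#' term (transferred update dotted into the next trial's error) to be
#' non-negative along the run. Pointwise non-negativity is exact only in
#' the self-averaged limit (for finite N the operator's anisotropy can
#' flip near-orthogonal target pairs), so the check is on the run-averaged
#' cross term, the quantity that drives the monotone decrease of the
#' total error; the worst single-trial value is reported alongside. The
#' simulated run starts from the solved baseline.
#'
#' @param dec a [decoder_sample()] with 2 outputs (`1/N` scaling).
#' @param task a [task_spec()].
#' @param eta learning rate.
#' @param enc an [input_encoding()] (default cosine).
#' @param tol negativity tolerance on the run-averaged cross term.
#' @return list with `ok` (mean cross term >= -tol), `mean_cross`,
#'   `min_cross` and the simulated learning-phase `errors`.
#' @export
multi_target_speed_check <- function(dec, task, eta,
                                     enc = input_encoding("cosine2d"),
                                     tol = 1e-10) {
  stopifnot(inherits(dec, "decoder_sample"), inherits(task, "task_spec"))
  if (enc$kind != "cosine2d") {
    stop_invalid("the solved-baseline start is defined for cosine2d encoding")
  }
  A <- build_A(dec)
  R <- rotation_matrix(task$rotation_angle)
  RARt <- R %*% A %*% t(R)
  # start from the baseline solution D W = radius * I
  W <- dec$n_neurons * t(dec$matrix) %*% solve(A) * task$target_radius
  state <- network_state(dec, input_dim = enc$n_units)
  state$weights <- W
  spec <- learning_spec(learning_rate = eta)
  idx <- make_target_sequence(task)
  learn_idx <- idx[task$n_baseline_trials + seq_len(task$n_learning_trials)]
  errors <- numeric(length(learn_idx))
  cross <- numeric(max(length(learn_idx) - 1L, 0L))
  prev_err <- NULL
  prev_theta <- NULL
  for (i in seq_along(learn_idx)) {
    theta <- task$target_angles[learn_idx[i]]
    x <- encode_direction(theta, enc)
    target <- task$target_radius * c(cos(theta), sin(theta))
    fwd <- forward(state, x, target, task$rotation_angle)
    errors[i] <- fwd$squared_error
    if (i > 1L) {
      g <- generalization_function(enc, theta - prev_theta)
      cross[i - 1L] <- g *
        sum(fwd$error_vector * drop(RARt %*% prev_err))
    }
    prev_err <- fwd$error_vector
    prev_theta <- theta
    state <- gradient_step(state, fwd, x, task$rotation_angle, spec)
  }
  min_cross <- if (length(cross)) min(cross) else 0
  mean_cross <- if (length(cross)) mean(cross) else 0
  list(ok = mean_cross >= -tol, mean_cross = mean_cross,
       min_cross = min_cross, errors = errors)
}

#' Theory summary table for a set of decoders
#'
#' One row per decoder sample: N, family, both eigenvalues, the predicted
#' exponential speed `-2 * log(max_k |1 - eta * lambda_k|)` (the
#' slowest-mode rate an exponential fit recovers in the noise-free limit)
#' and the optimal rate.
#'
#' @param decs list of [decoder_sample()] objects.
#' @param eta learning rate used for the predicted speed.
#' @return a data.frame.
#' @export
theory_table <- function(decs, eta = 0.2) {
  stopifnot(length(decs) > 0L)
  rows <- lapply(decs, function(d) {
    ev <- eigen(build_A(d), symmetric = TRUE, only.values = TRUE)$values
    data.frame(n_neurons = d$n_neurons, family = d$family,
               lambda_1 = max(ev), lambda_2 = min(ev),
               predicted_speed = -2 * log(max(abs(1 - eta * ev))),
               optimal_rate = tryCatch(optimal_learning_rate(ev),
                                       error = function(e) NA_real_))
  })
  do.call(rbind, rows)
}
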