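#' Define a center-out adaptation task
#'
#' A task is a set of K radially equidistant targets at a common radius, a
#' rotational perturbation (visuomotor rotation / curl-field analogue)
#' applied during the learning phase, and trial counts for the baseline
#' (unperturbed) and learning phases. The seeded target sequence is shared
#' across all conditions being compared so that paired contrasts see an
#' identical trial ordering.
#'
#' @param n_targets number of targets K (>= 1); target angles are exactly
#'   2*pi*k/K for k = 0..K-1.
#' @param target_radius length of each target vector (sets the error scale
#'   only; learning-speed results are radius-free).
#' @param rotation_angle perturbation angle phi in radians (a numeric, or a
#'   string with a "deg" suffix such as "45deg").
#' @param n_baseline_trials,n_learning_trials non-negative trial counts for
#'   the unperturbed and perturbed phases.
#' @param target_sequence_seed integer seed; the same seed always yields an
#'   identical target sequence.
#' @return an object of class `"task_spec"`.
#' @seealso [make_target_sequence()], [rotation_matrix()]
#' @export
#' @examples
#' task <- task_spec(n_targets = 8, rotation_angle = "45deg")
#' task$target_angles
task_spec <- function(n_targets = 8L, target_radius = 1,
                      rotation_angle = pi / 4,
                      n_baseline_trials = 100L, n_learning_trials = 100L,
                      target_sequence_seed = 1L) {
  check_scalar(n_targets, "n_targets", positive = TRUE, integerish = TRUE)
  check_scalar(target_radius, "target_radius", positive = TRUE)
  rotation_angle <- parse_angle(rotation_angle)
  check_angle(rotation_angle, "rotation_angle")
  check_scalar(n_baseline_trials, "n_baseline_trials", nonnegative = TRUE,
               integerish = TRUE)
  check_scalar(n_learning_trials, "n_learning_trials", nonnegative = TRUE,
               integerish = TRUE)
  check_scalar(target_sequence_seed, "target_sequence_seed",
               integerish = TRUE)
  K <- as.integer(n_targets)
  structure(list(
    n_targets = K,
    target_angles = 2 * pi * (seq_len(K) - 1L) / K,
    target_radius = target_radius,
    rotation_angle = rotation_angle,
    n_baseline_trials = as.integer(n_baseline_trials),
    n_learning_trials = as.integer(n_learning_trials),
    target_sequence_seed = as.integer(target_sequence_seed)
  ), class = "task_spec")
}

#' @export
print.task_spec <- function(x, ...) {
  cat(sprintf(
    "Task: %d targets, radius %.3g, rotation %.4g rad, %d baseline + %d learning trials (seed %d)\n",
    x$n_targets, x$target_radius, x$rotation_angle,
    x$n_baseline_trials, x$n_learning_trials, x$target_sequence_seed))
  invisible(x)
}

#' Define an input (direction) encoding
#'
#' Movement directions are encoded either as plain 2-D cosine inputs
#' (`cosine2d`: theta -> (cos theta, sin theta), the classical cosine-tuning
#' description of motor cortex inputs) or through a bank of von Mises-tuned
#' input units (`von_mises`), whose overlap between two encoded directions
#' defines the generalization function. Every encoded vector is normalized
#' to unit self-overlap so that g(0) = 1 and the encoding scale cannot
#' influence learning speed; the precision `kappa` alone then controls how
#' sharply adaptation at one direction transfers to others (large kappa =
#' narrow generalization, as in visuomotor rotation; small kappa = broad,
#' as in force fields).
#'
#' @param kind `"cosine2d"` or `"von_mises"`.
#' @param n_units number of von Mises input units M (preferred directions
#'   equally spaced on `[0, 2*pi)`); ignored for `cosine2d`, which always
#'   has 2 units.
#' @param kappa von Mises precision (> 0).
#' @return an object of class `"input_encoding"` with fields `kind`,
#'   `n_units`, `kappa`, `unit_preferred_dirs` and `normalization` (the
#'   norm of the unnormalized tuning vector at theta = 0, stored for
#'   reference).
#' @seealso [encode_direction()], [generalization_function()]
#' @export
input_encoding <- function(kind = c("cosine2d", "von_mises"),
                           n_units = 100L, kappa = 5) {
  kind <- match.arg(kind)
  if (kind == "cosine2d") {
    enc <- structure(list(kind = kind, n_units = 2L, kappa = NA_real_,
                          unit_preferred_dirs = c(0, pi / 2),
                          normalization = 1),
                     class = "input_encoding")
    return(enc)
  }
  check_scalar(n_units, "n_units", positive = TRUE, integerish = TRUE)
  check_scalar(kappa, "kappa", positive = TRUE)
  M <- as.integer(n_units)
  xi <- 2 * pi * (seq_len(M) - 1L) / M
  # exp(kappa * (cos - 1)) is the overflow-safe von Mises profile; the
  # constant exp(-kappa) cancels in the normalization.
  z0 <- sqrt(sum(exp(kappa * (cos(xi) - 1))^2))
  structure(list(kind = kind, n_units = M, kappa = kappa,
                 unit_preferred_dirs = xi, normalization = z0),
            class = "input_encoding")
}

#' @export
print.input_encoding <- function(x, ...) {
  if (x$kind == "cosine2d") cat("Encoding: 2-D cosine tuning\n")
  else cat(sprintf("Encoding: %d von Mises units, kappa = %.3g\n",
                   x$n_units, x$kappa))
  invisible(x)
}

#' Encode a movement direction as an input vector
#'
#' Deterministic in `(theta, enc)`; the returned vector has unit
#' self-overlap (squared norm 1) for every theta and precision.
#'
#' @param theta direction in radians (finite scalar).
#' @param enc an [input_encoding()].
#' @return numeric vector of length 2 (`cosine2d`) or `n_units`
#'   (`von_mises`).
#' @export
#' @examples
#' encode_direction(0, input_encoding("cosine2d"))      # c(1, 0)
encode_direction <- function(theta, enc) {
  stopifnot(inherits(enc, "input_encoding"))
  if (!is.numeric(theta) || length(theta) != 1L || !is.finite(theta)) {
    stop_invalid("`theta` must be a single finite angle")
  }
  if (enc$kind == "cosine2d") {
    return(c(cos(theta), sin(theta)))
  }
  v <- exp(enc$kappa * (cos(theta - enc$unit_preferred_dirs) - 1))
  v / sqrt(sum(v * v))
}

#' Generalization function g(delta)
#'
#' Overlap between the encodings of two directions separated by `delta`:
#' `g(delta) = <x(theta), x(theta + delta)>`. With unit-preferred
#' directions equally spaced this is (numerically) independent of theta;
#' g(0) = 1 by construction. For `cosine2d`, g(delta) = cos(delta), so an
#' update at one direction transfers with a cosine profile; for
#' `von_mises`, larger kappa gives a narrower g.
#'
#' @param enc an [input_encoding()].
#' @param delta angular separation(s), radians; vectorized.
#' @return numeric vector of overlaps in `[-1, 1]`.
#' @export
generalization_function <- function(enc, delta) {
  stopifnot(inherits(enc, "input_encoding"))
  check_angle(delta, "delta")
  if (enc$kind == "cosine2d") return(cos(delta))
  x0 <- encode_direction(0, enc)
  vapply(delta, function(d) sum(x0 * encode_direction(d, enc)), numeric(1))
}

#' 2-D rotation matrix
#'
#' Proper rotation by `phi` radians (determinant 1), used as the
#' visuomotor-rotation / curl-field perturbation between commanded force
#' and realized hand coordinate.
#'
#' @param phi rotation angle in radians (numeric or `"<x>deg"` string).
#' @return a 2 x 2 orthogonal matrix.
#' @export
#' @examples
#' rotation_matrix(pi / 2)   # maps (1,0) to (0,1)
rotation_matrix <- function(phi) {
  phi <- parse_angle(phi)
  check_scalar(phi, "phi")
  matrix(c(cos(phi), sin(phi), -sin(phi), cos(phi)), 2L, 2L)
}

#' Seeded target sequence for a task
#'
#' Draws a uniform random sequence of target indices of length
#' `n_baseline_trials + n_learning_trials`, reproducible from
#' `target_sequence_seed`. All conditions built from the same task spec
#' therefore share one identical target sequence.
#'
#' @param spec a [task_spec()].
#' @return integer vector of 1-based target indices in `1..K`.
#' @export
make_target_sequence <- function(spec) {
  stopifnot(inherits(spec, "task_spec"))
  if (spec$n_targets < 1L) stop_invalid("task has zero targets")
  n <- spec$n_baseline_trials + spec$n_learning_trials
  with_seed(spec$target_sequence_seed,
            sample.int(spec$n_targets, n, replace = TRUE))
}
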