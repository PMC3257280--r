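#' Define an experiment condition
#'
#' A condition bundles everything needed to run repetitions: the decoder
#' distribution and population size, the task and encoding, the learning
#' rule and noise, plus structural variants. Two modes are supported:
#'
#' * `"rotation"` (default): center-out targets with angular encodings and
#'   a rotation perturbation during the learning phase.
#' * `"highdim"`: `n_tasks` task input/target pairs with fixed random
#'   unit-norm inputs (dimension `input_dim`, default `n_tasks`) and
#'   planar targets under a common rotation; used with the
#'   `gaussian_highdim` decoder family to vary the redundancy gap between
#'   N and T directly.
#'
#' @param label condition label (character).
#' @param n_neurons population size N.
#' @param dist a [decoder_distribution()].
#' @param task a [task_spec()].
#' @param enc an [input_encoding()] (rotation mode).
#' @param learning a [learning_spec()].
#' @param noise a [noise_spec()].
#' @param activation `"linear"` or `"saturating"`.
#' @param recurrent_radius spectral radius of random fixed recurrent
#'   connections (0 = feed-forward; entries i.i.d. Gaussian scaled to the
#'   requested radius, resampled per repetition).
#' @param n_muscles 0 for the linear decoder readout, or an even muscle
#'   count for the rectified readout.
#' @param adaptable_decoder logical; pairs with `learning$decoder_rate`.
#' @param mode `"rotation"` or `"highdim"`.
#' @param n_tasks number of constrained tasks T (highdim mode).
#' @param input_dim input dimension for highdim mode (default `n_tasks`;
#'   a warning is raised if `n_tasks` exceeds it, since extra tasks are
#'   then rank-deficient).
#' @return an object of class `"experiment_condition"`.
#' @export
experiment_condition <- function(label, n_neurons,
                                 dist = decoder_distribution("homogeneous_uniform"),
                                 task = task_spec(),
                                 enc = input_encoding("cosine2d"),
                                 learning = learning_spec(),
                                 noise = noise_spec(),
                                 activation = "linear",
                                 recurrent_radius = 0,
                                 n_muscles = 0L,
                                 adaptable_decoder = FALSE,
                                 mode = c("rotation", "highdim"),
                                 n_tasks = NULL, input_dim = NULL) {
  mode <- match.arg(mode)
  check_scalar(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  check_scalar(recurrent_radius, "recurrent_radius", nonnegative = TRUE)
  if (recurrent_radius >= 1) stop_invalid("`recurrent_radius` must be < 1")
  if (mode == "highdim") {
    if (is.null(n_tasks)) stop_invalid("highdim mode requires `n_tasks`")
    check_scalar(n_tasks, "n_tasks", positive = TRUE, integerish = TRUE)
    if (is.null(input_dim)) input_dim <- n_tasks
    check_scalar(input_dim, "input_dim", positive = TRUE, integerish = TRUE)
    if (n_tasks > input_dim) {
      warning("n_tasks exceeds input_dim: task set is rank-deficient",
              call. = FALSE)
    }
  }
  structure(list(label = as.character(label),
                 n_neurons = as.integer(n_neurons), dist = dist,
                 task = task, enc = enc, learning = learning,
                 noise = noise, activation = activation,
                 recurrent_radius = recurrent_radius,
                 n_muscles = as.integer(n_muscles),
                 adaptable_decoder = isTRUE(adaptable_decoder),
                 mode = mode,
                 n_tasks = if (is.null(n_tasks)) NA_integer_
                           else as.integer(n_tasks),
                 input_dim = if (is.null(input_dim)) NA_integer_
                             else as.integer(input_dim)),
            class = "experiment_condition")
}

# one trial-by-trial update according to the condition's rule
apply_rule <- function(state, fwd, x, target, phi, cond) {
  spec <- cond$learning
  state <- switch(spec$rule,
    gradient = gradient_step(state, fwd, x, phi, spec, cond$noise),
    weight_perturbation =
      weight_perturbation_step(state, x, target, phi, spec, cond$noise),
    node_perturbation =
      node_perturbation_step(state, x, target, phi, spec, cond$noise))
  if (cond$adaptable_decoder && spec$decoder_rate > 0) {
    state <- decoder_step(state, fwd, spec, cond$noise)
  }
  state
}

#' Run one repetition of a condition
#'
#' Samples a fresh decoder from the repetition seed, runs the baseline
#' phase (rotation 0) followed by the learning phase (rotation
#' `task$rotation_angle`), and returns the learning-phase squared errors.
#' All randomness (decoder, recurrent weights, noise, perturbations) is
#' driven by `repetition_seed`, so the same condition and seed reproduce
#' the curve bitwise; the target sequence comes from the task's own seed
#' and is shared across conditions.
#'
#' @param cond an [experiment_condition()].
#' @param repetition_seed integer seed for this repetition.
#' @return an object of class `"learning_curve"`: list with `errors`
#'   (learning phase only), `condition_label`, `repetition_seed`,
#'   `diverged`, and `final_state` (the network state after the run).
#' @export
run_repetition <- function(cond, repetition_seed) {
  stopifnot(inherits(cond, "experiment_condition"))
  task <- cond$task
  idx <- make_target_sequence(task)
  n_base <- task$n_baseline_trials
  n_learn <- task$n_learning_trials
  with_seed(repetition_seed, {
    dec <- sample_decoder(cond$dist, cond$n_neurons)
    if (cond$mode == "highdim") {
      # random orthonormal task frame: unit-norm inputs whose pairwise
      # overlaps vanish, so T nominal tasks are T effective constraints
      G <- matrix(rnorm(cond$input_dim * cond$input_dim),
                  cond$input_dim, cond$input_dim)
      X <- qr.Q(qr(G))[, seq_len(min(cond$n_tasks, cond$input_dim)),
                       drop = FALSE]
      if (cond$n_tasks > cond$input_dim) {   # rank-deficient extras
        extra <- matrix(rnorm(cond$input_dim *
                                (cond$n_tasks - cond$input_dim)),
                        cond$input_dim)
        extra <- sweep(extra, 2L, sqrt(colSums(extra^2)), `/`)
        X <- cbind(X, extra)
      }
      ang <- 2 * pi * (seq_len(cond$n_tasks) - 1L) / cond$n_tasks
      targets <- task$target_radius * rbind(cos(ang), sin(ang))
      idx <- with_seed(task$target_sequence_seed,
                       sample.int(cond$n_tasks, n_base + n_learn,
                                  replace = TRUE))
      input_dim <- cond$input_dim
    } else {
      input_dim <- cond$enc$n_units
      targets <- task$target_radius *
        rbind(cos(task$target_angles), sin(task$target_angles))
    }
    recurrent <- NULL
    if (cond$recurrent_radius > 0) {
      N <- cond$n_neurons
      K <- matrix(rnorm(N * N), N, N)
      K <- K * (cond$recurrent_radius / spectral_radius(K))
      recurrent <- K
    }
    muscle <- if (cond$n_muscles > 0L) {
      make_muscle_set(cond$n_neurons, cond$n_muscles)
    } else NULL
    state <- network_state(dec, input_dim = input_dim,
                           activation = cond$activation,
                           recurrent = recurrent, muscle = muscle,
                           adaptable_decoder = cond$adaptable_decoder)
    errors <- rep(NA_real_, n_learn)
    diverged <- FALSE
    e_ref <- NA_real_
    for (i in seq_len(n_base + n_learn)) {
      learning_phase <- i > n_base
      phi <- if (learning_phase) task$rotation_angle else 0
      k <- idx[i]
      x <- if (cond$mode == "highdim") X[, k]
           else encode_direction(task$target_angles[k], cond$enc)
      target <- targets[, k]
      fwd <- forward(state, x, target, phi, cond$noise)
      if (learning_phase) {
        errors[i - n_base] <- fwd$squared_error
        if (is.na(e_ref)) e_ref <- max(fwd$squared_error, 1e-12)
        if (!is.finite(fwd$squared_error) ||
            fwd$squared_error > 1e6 * e_ref) {
          diverged <- TRUE
          break
        }
      }
      state <- apply_rule(state, fwd, x, target, phi, cond)
    }
    structure(list(errors = errors, condition_label = cond$label,
                   repetition_seed = as.integer(repetition_seed),
                   diverged = diverged, final_state = state),
              class = "learning_curve")
  })
}

#' @export
print.learning_curve <- function(x, ...) {
  cat(sprintf("Learning curve '%s' (seed %d): %d trials%s\n",
              x$condition_label, x$repetition_seed, length(x$errors),
              if (isTRUE(x$diverged)) ", DIVERGED" else ""))
  if (length(x$errors)) {
    cat(sprintf("  first/last squared error: %.4g / %.4g\n",
                x$errors[1L], x$errors[length(x$errors)]))
  }
  invisible(x)
}

#' Fit an exponential to a learning curve
#'
#' Fits `a * exp(-s * t) + c` (t = 0, 1, ... over learning trials) with
#' `a >= 0`, `s >= 0`, `c >= 0` by least squares on the logarithmic scale:
#' squared-error curves span several decades, and log-domain residuals
#' weight the late, slow-mode trials -- where the smaller eigenvalue of
#' the learning operator expresses itself -- on a par with the large early
#' errors (an absolute-scale fit is dominated by the first few trials and
#' reports a mixture rate instead). The rate s is the learning speed.
#' Optimization is multi-start (an absolute-scale profile fit and
#' log-slope estimates seed a box-constrained quasi-Newton search), so the
#' result does not depend on initial values. A curve with no decreasing
#' trend gets `s = 0`.
#'
#' @param curve a `"learning_curve"` or a numeric vector of squared
#'   errors.
#' @param s_max largest rate searched.
#' @return an object of class `"speed_fit"`: list with `speed`,
#'   `amplitude`, `offset`, `fit_residual` (log-scale residual sum of
#'   squares) and `converged`.
#' @export
fit_speed <- function(curve, s_max = 10) {
  y <- if (inherits(curve, "learning_curve")) curve$errors else as.numeric(curve)
  if (inherits(curve, "learning_curve") && isTRUE(curve$diverged)) {
    return(structure(list(speed = NA_real_, amplitude = NA_real_,
                          offset = NA_real_, fit_residual = NA_real_,
                          converged = FALSE), class = "speed_fit"))
  }
  y <- y[is.finite(y)]
  n <- length(y)
  if (n < 10L) stop_invalid("need at least 10 trials to fit a speed")
  tt <- seq_len(n) - 1
  flat <- structure(list(speed = 0, amplitude = 0, offset = mean(y),
                         fit_residual = var(log(pmax(y, 1e-300))) * (n - 1),
                         converged = TRUE), class = "speed_fit")
  if (max(y) - min(y) <= 1e-14 * max(abs(y), 1)) {
    flat$fit_residual <- 0
    return(flat)
  }
  tiny <- max(min(y[y > 0], na.rm = TRUE) * 1e-6, 1e-300)
  ly <- log(pmax(y, tiny))
  obj <- function(p) {
    m <- p[2L] * exp(-p[1L] * tt) + p[3L]
    sum((log(pmax(m, tiny)) - ly)^2)
  }
  # absolute-scale profile fit, used as one starting point
  abs_profile <- function(s) {
    z <- exp(-s * tt)
    zc <- z - mean(z)
    denom <- sum(zc^2)
    a <- if (denom < 1e-300) 0 else sum(zc * (y - mean(y))) / denom
    max(a, 0)
  }
  grid <- exp(seq(log(1e-4), log(s_max), length.out = 40L))
  rss_abs <- vapply(grid, function(s) {
    a <- abs_profile(s)
    c0 <- mean(y) - a * mean(exp(-s * tt))
    sum((y - a * exp(-s * tt) - c0)^2)
  }, numeric(1))
  s_abs <- grid[which.min(rss_abs)]
  # log-slope starts over the full curve and its first half
  slope_start <- function(idx) {
    fitc <- stats::lm.fit(cbind(1, tt[idx]), ly[idx])$coefficients
    max(-unname(fitc[2L]), 1e-4)
  }
  s_starts <- unique(c(s_abs, slope_start(seq_len(n)),
                       slope_start(seq_len(max(10L, n %/% 2)))))
  best <- NULL
  for (s0 in s_starts) {
    p0 <- c(min(s0, s_max), max(y[1L] - min(y), tiny), max(min(y), 0))
    fit <- tryCatch(
      stats::optim(p0, obj, method = "L-BFGS-B",
                   lower = c(0, 0, 0), upper = c(s_max, Inf, Inf),
                   control = list(factr = 10, maxit = 1000L)),
      error = function(e) NULL)
    if (!is.null(fit) && (is.null(best) || fit$value < best$value)) {
      best <- fit
    }
  }
  if (!is.null(best)) {   # derivative-free polish off the box constraints
    pol <- tryCatch(
      stats::optim(best$par, obj, method = "Nelder-Mead",
                   control = list(reltol = 1e-14, maxit = 2000L)),
      error = function(e) NULL)
    if (!is.null(pol) && pol$value <= best$value &&
        all(pol$par >= 0) && pol$par[1L] <= s_max) {
      best <- pol
    }
  }
  if (is.null(best) || best$par[2L] <= tiny ||
      best$value >= flat$fit_residual) {
    return(flat)
  }
  structure(list(speed = best$par[1L], amplitude = best$par[2L],
                 offset = best$par[3L], fit_residual = best$value,
                 converged = best$convergence == 0L),
            class = "speed_fit")
}

#' @export
print.speed_fit <- function(x, ...) {
  cat(sprintf("Speed fit: s = %.5g, a = %.4g, c = %.4g (rss %.4g)\n",
              x$speed, x$amplitude, x$offset, x$fit_residual))
  invisible(x)
}

#' Across-repetition variance of learning curves
#'
#' The stability measure: unbiased variance of the squared error across
#' repetitions, computed per learning trial and averaged over trials.
#' Lower values mean learning is more reproducible from repetition to
#' repetition.
#'
#' @param curves list of `"learning_curve"` objects (or numeric vectors)
#'   of equal length; at least 2.
#' @return non-negative scalar.
#' @export
curve_variance <- function(curves) {
  errs <- lapply(curves, function(cv) {
    if (inherits(cv, "learning_curve")) cv$errors else as.numeric(cv)
  })
  if (length(errs) < 2L) stop_invalid("need at least 2 curves")
  lens <- lengths(errs)
  if (length(unique(lens)) != 1L) stop_invalid("curves differ in length")
  mat <- do.call(rbind, errs)
  mean(apply(mat, 2L, var))
}

#' Run many repetitions of one condition
#'
#' @param cond an [experiment_condition()].
#' @param n_reps number of repetitions.
#' @param base_seed repetition seeds are `base_seed + 1..n_reps`, so two
#'   conditions run with the same `base_seed` are paired by seed.
#' @return list with `curves`, `speeds` (fitted, `NA` for diverged
#'   repetitions), and `n_excluded` (diverged count).
#' @export
run_condition <- function(cond, n_reps, base_seed = 0L) {
  check_scalar(n_reps, "n_reps", positive = TRUE, integerish = TRUE)
  curves <- lapply(seq_len(n_reps),
                   function(r) run_repetition(cond, base_seed + r))
  speeds <- vapply(curves, function(cv) fit_speed(cv)$speed, numeric(1))
  list(curves = curves, speeds = speeds,
       n_excluded = sum(vapply(curves, function(cv) cv$diverged, logical(1))))
}

#' Learning speed as a function of neuronal redundancy
#'
#' Runs `n_reps` paired repetitions at each population size and summarizes
#' the fitted speeds; repetitions are paired by seed across sizes to
#' maximize the power of signed-rank contrasts. A saturating power fit
#' `s(N) = s_inf - b * N^(-beta)` of the mean speeds is attached.
#'
#' @param n_values integer vector of population sizes.
#' @param n_reps repetitions per size.
#' @param base_seed pairing seed base.
#' @param ... further arguments passed to [experiment_condition()] (e.g.
#'   `dist`, `task`, `enc`, `learning`, `noise`, `adaptable_decoder`).
#' @return a data.frame with one row per N (`n_neurons`, `mean_speed`,
#'   `sd_speed`, `n_excluded`); attribute `"speeds"` holds the per-N speed
#'   vectors and `"power_fit"` the `(s_inf, b, beta)` coefficients.
#' @export
redundancy_sweep <- function(n_values, n_reps = 200L, base_seed = 0L, ...) {
  runs <- lapply(n_values, function(N) {
    run_condition(experiment_condition(label = paste0("N", N),
                                       n_neurons = N, ...),
                  n_reps, base_seed)
  })
  speeds <- lapply(runs, function(r) r$speeds)
  names(speeds) <- paste0("N", n_values)
  out <- data.frame(
    n_neurons = as.integer(n_values),
    mean_speed = vapply(speeds, function(s) mean(s, na.rm = TRUE), numeric(1)),
    sd_speed = vapply(speeds, function(s) sd(s, na.rm = TRUE), numeric(1)),
    n_excluded = vapply(runs, function(r) r$n_excluded, integer(1)))
  attr(out, "speeds") <- speeds
  if (length(n_values) >= 3L) {
    fit_beta <- function(beta) {
      z <- as.numeric(n_values)^(-beta)
      r <- stats::lm.fit(cbind(1, z), out$mean_speed)
      sum(r$residuals^2)
    }
    beta <- optimize(fit_beta, c(0.05, 3))$minimum
    co <- stats::lm.fit(cbind(1, as.numeric(n_values)^(-beta)),
                        out$mean_speed)$coefficients
    attr(out, "power_fit") <- c(s_inf = unname(co[1L]), b = -unname(co[2L]),
                                beta = beta)
  }
  out
}

#' Learning speed across the (N, T) redundancy grid
#'
#' High-dimensional task sets with `gaussian_highdim` decoders: T fixed
#' unit-norm random inputs with planar targets under a common rotation.
#' Redundancy is the gap between N and T, so speed should fall with T at
#' fixed N and rise with N at fixed T.
#'
#' @param n_values population sizes.
#' @param t_values task counts.
#' @param n_reps repetitions per cell (paired by seed across cells).
#' @param base_seed pairing seed base.
#' @param task a [task_spec()] (rotation, radius and trial counts reused).
#' @param learning a [learning_spec()].
#' @param noise a [noise_spec()].
#' @return data.frame with one row per (N, T) cell; attribute `"speeds"`
#'   holds the per-cell speed vectors keyed `"N<k>_T<j>"`.
#' @export
redundancy_vs_tasks_sweep <- function(n_values, t_values, n_reps = 200L,
                                      base_seed = 0L, task = task_spec(),
                                      learning = learning_spec(),
                                      noise = noise_spec()) {
  grid <- expand.grid(n_neurons = as.integer(n_values),
                      n_tasks = as.integer(t_values))
  speeds <- list()
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    N <- grid$n_neurons[i]; Tt <- grid$n_tasks[i]
    cond <- experiment_condition(
      label = sprintf("N%d_T%d", N, Tt), n_neurons = N,
      dist = decoder_distribution("gaussian_highdim"),
      task = task, learning = learning, noise = noise,
      mode = "highdim", n_tasks = Tt)
    run <- run_condition(cond, n_reps, base_seed)
    speeds[[cond$label]] <<- run$speeds
    data.frame(n_neurons = N, n_tasks = Tt,
               mean_speed = mean(run$speeds, na.rm = TRUE),
               sd_speed = sd(run$speeds, na.rm = TRUE),
               n_excluded = run$n_excluded)
  })
  out <- do.call(rbind, rows)
  attr(out, "speeds") <- speeds
  out
}

#' Paired signed-rank comparison of two speed samples
#'
#' Wilcoxon signed-rank test on repetition-paired samples, plus the effect
#' direction (sign of the median paired difference `b - a`). Identical
#' samples return p = 1 and zero effect.
#'
#' @param speeds_a,speeds_b numeric vectors paired by repetition seed.
#' @return list with `statistic`, `p_value`, `direction` (-1, 0, 1) and
#'   `n` (number of pairs).
#' @export
compare_conditions <- function(speeds_a, speeds_b) {
  if (length(speeds_a) != length(speeds_b)) {
    stop_invalid("samples must be paired (equal length)")
  }
  keep <- is.finite(speeds_a) & is.finite(speeds_b)
  a <- speeds_a[keep]; b <- speeds_b[keep]
  d <- b - a
  if (all(d == 0)) {
    return(list(statistic = 0, p_value = 1, direction = 0L,
                n = length(d)))
  }
  wt <- suppressWarnings(wilcox.test(b, a, paired = TRUE))
  list(statistic = unname(wt$statistic), p_value = wt$p.value,
       direction = as.integer(sign(median(d))), n = length(d))
}
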