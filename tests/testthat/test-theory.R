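test_that("analytic curves reproduce hand-derived closed forms", {
  A <- diag(2) / 2
  expect_equal(analytic_curve(A, 0, c(1, 0), 5), rep(0.5, 5))
  # isotropic operator, eta 0.2: E_t = 0.81^t * E_0 with E_0 = 1/2
  expect_equal(analytic_curve(A, 0.2, c(1, 0), 6), 0.5 * 0.81^(0:5),
               tolerance = 1e-14)
  # eigenbasis change preserves the initial error
  set.seed(1)
  for (i in 1:20) {
    B <- matrix(rnorm(4), 2); Asym <- crossprod(B)
    e0 <- rnorm(2)
    expect_equal(analytic_curve(Asym, 0.13, e0, 3)[1], 0.5 * sum(e0^2),
                 tolerance = 1e-12)
  }
})

test_that("the simulator reproduces the analytic curve to high precision", {
  task <- task_spec(n_targets = 1, n_baseline_trials = 0,
                    n_learning_trials = 100)
  R <- rotation_matrix(task$rotation_angle)
  for (s in 1:10) {
    cond <- experiment_condition("eq", 100, task = task)
    cv <- run_repetition(cond, s)
    A <- build_A(cv$final_state$decoder)
    th <- analytic_curve(R %*% A %*% t(R), 0.2, c(1, 0), 100)
    expect_lt(max(abs(cv$errors - th) / th), 1e-10)
  }
})

test_that("learning-speed bound: attainment iff the operator is isotropic", {
  b <- learning_speed_bound(decoder_from_angles(c(0, pi / 2)))
  expect_equal(b$lambda_min, 0.5, tolerance = 1e-12)
  expect_true(b$is_maximal)
  b1 <- learning_speed_bound(decoder_from_angles(0.7))
  expect_equal(b1$lambda_min, 0, tolerance = 1e-12)
  expect_false(b1$is_maximal)
})

test_that("redundancy drives the smaller eigenvalue toward its bound", {
  dist <- decoder_distribution("homogeneous_uniform")
  frac_near <- vapply(c(10, 100, 1000), function(N) {
    mean(vapply(1:200, function(s) {
      learning_speed_bound(sample_decoder(dist, N, seed = 300 + s))$lambda_min > 0.45
    }, logical(1)))
  }, numeric(1))
  expect_true(all(diff(frac_near) > 0))
})

test_that("closed-form optimal rate matches a grid-search oracle", {
  expect_equal(optimal_learning_rate(c(0.5, 0.5)), 2)
  expect_equal(optimal_learning_rate(c(0.6, 0.4)), 2)
  expect_equal(max(abs(1 - 2 * c(0.6, 0.4))), 0.2)
  expect_equal(optimal_learning_rate(0.8), 1 / 0.8)
  expect_error(optimal_learning_rate(c(0, 0)), "no learning")
  set.seed(2)
  etas <- seq(1e-3, 4, length.out = 8000)
  for (i in 1:100) {
    lam <- sort(runif(2, 0.25, 1), decreasing = TRUE)
    worst <- vapply(etas, function(eta) max((1 - eta * lam)^2), numeric(1))
    eta_grid <- etas[which.min(worst)]
    expect_lt(abs(optimal_learning_rate(lam) - eta_grid),
              2 * (etas[2] - etas[1]))
  }
})

test_that("residual error under decay matches long-run simulation and vanishes without decay", {
  expect_equal(residual_error_with_decay(diag(2) / 2, 0.2, 0, 0, c(1, 0), 10),
               0)
  set.seed(3)
  for (i in 1:5) {
    N <- 40
    dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), N)
    A <- build_A(dec)
    decay <- runif(1, 0.01, 0.08)
    drift <- if (i <= 3) 0 else 0.02
    phi <- pi / 4
    R <- rotation_matrix(phi)
    tgt <- c(1, 0)
    pred <- residual_error_with_decay(R %*% A %*% t(R), 0.2, decay, drift,
                                      tgt, N)
    st <- network_state(dec, 2)
    spec <- learning_spec(decay = decay, drift_sd = drift)
    x <- c(1, 0)
    tail_sum <- 0; tail_n <- 0
    for (t in 1:5000) {
      fwd <- forward(st, x, tgt, phi)
      if (t > 3000) { tail_sum <- tail_sum + fwd$squared_error
                      tail_n <- tail_n + 1 }
      st <- gradient_step(st, fwd, x, phi, spec)
    }
    expect_equal(tail_sum / tail_n, pred, tolerance = 0.02)
  }
  expect_error(residual_error_with_decay(diag(2), 2, 0.5, 0, c(1, 0), 10),
               "unstable")
})

test_that("single-trial command transfer matches simulation and the generalization profile", {
  dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), 200,
                        seed = 4)
  A <- build_A(dec)
  enc <- input_encoding("cosine2d")
  phi <- pi / 4
  st <- network_state(dec, 2)
  set.seed(4)
  st$weights <- matrix(rnorm(400, sd = 0.3), 200, 2)
  th_tr <- 0.5
  x_tr <- encode_direction(th_tr, enc)
  tgt <- c(cos(th_tr), sin(th_tr))
  fwd <- forward(st, x_tr, tgt, phi)
  s2 <- gradient_step(st, fwd, x_tr, phi, learning_spec())
  for (th_pr in c(th_tr, th_tr + pi / 2, th_tr + 0.9)) {
    x_pr <- encode_direction(th_pr, enc)
    dy <- forward(s2, x_pr, tgt, phi)$hand - forward(st, x_pr, tgt, phi)$hand
    pred <- command_update_prediction(A, enc, th_tr, th_pr, 0.2,
                                      fwd$error_vector, phi)
    expect_equal(dy, pred, tolerance = 1e-8)
  }
  # orthogonal probe receives nothing under cosine tuning
  pred_perp <- command_update_prediction(A, enc, th_tr, th_tr + pi / 2, 0.2,
                                         fwd$error_vector, phi)
  expect_equal(pred_perp, c(0, 0), tolerance = 1e-12)
  # narrow von Mises tuning transfers less at pi/4 than broad tuning
  enc_b <- input_encoding("von_mises", 100, kappa = 1)
  enc_n <- input_encoding("von_mises", 100, kappa = 20)
  p_b <- command_update_prediction(A, enc_b, th_tr, th_tr + pi / 4, 0.2,
                                   fwd$error_vector, phi)
  p_n <- command_update_prediction(A, enc_n, th_tr, th_tr + pi / 4, 0.2,
                                   fwd$error_vector, phi)
  expect_lt(sqrt(sum(p_n^2)), sqrt(sum(p_b^2)))
  # the von Mises transfer prediction also matches simulation
  stv <- network_state(dec, input_dim = 100)
  set.seed(5)
  stv$weights <- matrix(rnorm(200 * 100, sd = 0.05), 200, 100)
  xv <- encode_direction(th_tr, enc_n)
  fwdv <- forward(stv, xv, tgt, phi)
  s2v <- gradient_step(stv, fwdv, xv, phi, learning_spec())
  xp <- encode_direction(th_tr + pi / 4, enc_n)
  dyv <- forward(s2v, xp, tgt, phi)$hand - forward(stv, xp, tgt, phi)$hand
  predv <- command_update_prediction(A, enc_n, th_tr, th_tr + pi / 4, 0.2,
                                     fwdv$error_vector, phi)
  expect_equal(dyv, predv, tolerance = 1e-8)
})

test_that("multi-target cross terms stay aligned under rotational perturbations", {
  task0 <- task_spec(rotation_angle = 0, n_baseline_trials = 0,
                     n_learning_trials = 40)
  dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), 100,
                        seed = 6)
  chk0 <- multi_target_speed_check(dec, task0, 0.2)
  expect_true(chk0$ok)
  expect_true(all(chk0$errors < 1e-20))
  task <- task_spec(n_baseline_trials = 0, n_learning_trials = 60)
  chk <- multi_target_speed_check(dec, task, 0.2)
  expect_true(chk$ok)
  expect_gt(chk$mean_cross, 0)
  expect_gt(chk$errors[1], 0)
})

test_that("elementwise-ordered spectra give pointwise-ordered analytic curves and eta-robust rankings", {
  e0 <- c(1, 1) / sqrt(2)
  curve_fast <- analytic_curve(diag(c(0.5, 0.45)), 0.2, e0, 50)
  curve_slow <- analytic_curve(diag(c(0.45, 0.2)), 0.2, e0, 50)
  expect_true(all(curve_fast <= curve_slow + 1e-15))
  lam_sets <- list(c(0.5, 0.48), c(0.5, 0.35), c(0.6, 0.15), c(0.7, 0.05))
  speed <- function(lam, eta) -2 * log(max(abs(1 - eta * lam)))
  rank_at <- function(eta) order(vapply(lam_sets, speed, numeric(1),
                                        eta = eta))
  base <- rank_at(0.2)
  expect_identical(rank_at(0.05), base)
  opt <- order(vapply(lam_sets, function(l) {
    speed(l, optimal_learning_rate(l))
  }, numeric(1)))
  expect_identical(opt, base)
})

test_that("theory tables summarize spectra and predicted speeds per decoder", {
  decs <- lapply(1:5, function(s) {
    sample_decoder(decoder_distribution("homogeneous_uniform"), 50, seed = s)
  })
  tab <- theory_table(decs, eta = 0.2)
  expect_equal(nrow(tab), 5L)
  expect_true(all(tab$lambda_1 >= tab$lambda_2))
  expect_equal(tab$predicted_speed,
               -2 * log(pmax(abs(1 - 0.2 * tab$lambda_1),
                             abs(1 - 0.2 * tab$lambda_2))),
               tolerance = 1e-12)
})
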