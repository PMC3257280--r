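# deterministic squared error as a function of the weights, for oracles
err_at <- function(state, W, x, tgt, phi) {
  state$weights <- W
  forward(state, x, tgt, phi)$squared_error
}

num_grad <- function(state, W, x, tgt, phi, h = 1e-6) {
  G <- W
  for (i in seq_along(W)) {
    Wp <- W; Wm <- W
    Wp[i] <- W[i] + h; Wm[i] <- W[i] - h
    G[i] <- (err_at(state, Wp, x, tgt, phi) -
               err_at(state, Wm, x, tgt, phi)) / (2 * h)
  }
  G
}

random_instance <- function(kind, seed) {
  set.seed(seed)
  N <- 6L
  dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), N)
  state <- switch(kind,
    linear = network_state(dec, 2),
    saturating = network_state(dec, 2, activation = "saturating"),
    recurrent = {
      K <- matrix(rnorm(N * N, sd = 0.1), N, N)
      K <- K * 0.6 / redmotor:::spectral_radius(K)
      network_state(dec, 2, recurrent = K)
    },
    muscle = network_state(dec, 2, muscle = make_muscle_set(N, 6)))
  state$weights <- matrix(rnorm(2 * N), N, 2)
  list(state = state, x = c(cos(0.4), sin(0.4)), tgt = c(1.2, -0.5),
       phi = pi / 4)
}

test_that("the gradient step moves exactly along the negative numerical gradient", {
  kinds <- rep(c("linear", "saturating", "recurrent", "muscle"), each = 5)
  spec <- learning_spec(learning_rate = 0.1)
  for (i in seq_along(kinds)) {
    inst <- random_instance(kinds[i], 100 + i)
    st <- inst$state
    if (kinds[i] == "muscle") {
      # keep drives away from the rectifier kink so the derivative exists
      drv <- drop(st$muscle$matrix %*%
                    forward(st, inst$x, inst$tgt, inst$phi)$activities)
      if (min(abs(drv)) < 1e-4) next
    }
    fwd <- forward(st, inst$x, inst$tgt, inst$phi)
    s2 <- gradient_step(st, fwd, inst$x, inst$phi, spec)
    dW <- s2$weights - st$weights
    expected <- -st$decoder$n_neurons * 0.1 *
      num_grad(st, st$weights, inst$x, inst$tgt, inst$phi)
    expect_equal(dW, expected, tolerance = 1e-4)
  }
})

test_that("zero error is a fixed point and small rates descend monotonically", {
  dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), 30,
                        seed = 2)
  state <- network_state(dec, 2)
  A <- build_A(dec)
  state$weights <- dec$n_neurons * t(dec$matrix) %*% solve(A)
  x <- c(1, 0)
  fwd <- forward(state, x, x, 0)
  expect_equal(fwd$squared_error, 0, tolerance = 1e-24)
  s2 <- gradient_step(state, fwd, x, 0, learning_spec())
  expect_equal(s2$weights, state$weights)
  # descent from scratch
  state <- network_state(dec, 2)
  spec <- learning_spec(learning_rate = 0.05)
  errs <- numeric(50)
  for (t in 1:50) {
    fwd <- forward(state, x, c(1, 0), pi / 4)
    errs[t] <- fwd$squared_error
    state <- gradient_step(state, fwd, x, pi / 4, spec)
  }
  expect_true(all(diff(errs) < 0))
})

test_that("adaptable-decoder updates leave zero-error states alone and descend jointly", {
  dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), 12,
                        seed = 3)
  fixed <- network_state(dec, 2)
  fwd0 <- forward(fixed, c(1, 0), c(0, 0), 0)   # zero target, zero output
  expect_error(decoder_step(fixed, fwd0, learning_spec(decoder_rate = 0.1)),
               "fixed-decoder")
  ad <- network_state(dec, 2, adaptable_decoder = TRUE)
  spec <- learning_spec(learning_rate = 0.05, decoder_rate = 0.1)
  expect_equal(decoder_step(ad, fwd0, spec)$decoder$matrix, dec$matrix)
  set.seed(3)
  for (i in 1:20) {
    st <- network_state(
      sample_decoder(decoder_distribution("homogeneous_uniform"), 12),
      2, adaptable_decoder = TRUE)
    st$weights <- matrix(rnorm(24, sd = 0.5), 12, 2)
    x <- c(cos(1), sin(1)); tgt <- c(0.5, 1); phi <- pi / 6
    fwd <- forward(st, x, tgt, phi)
    s2 <- decoder_step(gradient_step(st, fwd, x, phi, spec), fwd, spec)
    expect_lt(forward(s2, x, tgt, phi)$squared_error, fwd$squared_error)
  }
})

test_that("perturbation rules are unbiased gradient estimators", {
  inst <- random_instance("linear", 7)
  st <- inst$state
  spec_wp <- learning_spec(learning_rate = 0.1, rule = "weight_perturbation",
                           perturbation_sd = 0.01)
  spec_np <- learning_spec(learning_rate = 0.1, rule = "node_perturbation",
                           perturbation_sd = 0.01)
  G <- num_grad(st, st$weights, inst$x, inst$tgt, inst$phi)
  expected <- -st$decoder$n_neurons * 0.1 * G
  for (spec in list(spec_wp, spec_np)) {
    set.seed(11)
    n_draws <- 20000
    acc <- matrix(0, nrow(st$weights), ncol(st$weights))
    acc2 <- acc
    for (k in seq_len(n_draws)) {
      s2 <- if (spec$rule == "weight_perturbation") {
        weight_perturbation_step(st, inst$x, inst$tgt, inst$phi, spec)
      } else {
        node_perturbation_step(st, inst$x, inst$tgt, inst$phi, spec)
      }
      dW <- s2$weights - st$weights
      acc <- acc + dW
      acc2 <- acc2 + dW^2
    }
    m <- acc / n_draws
    se <- sqrt(pmax(acc2 / n_draws - m^2, 0) / n_draws)
    expect_true(all(abs(m - expected) < 3 * se + 1e-12))
  }
  expect_error(learning_spec(rule = "node_perturbation",
                             perturbation_sd = 0), "perturbation_sd")
})

test_that("a flat error landscape yields a null node-perturbation update", {
  zero_dec <- sample_decoder(
    decoder_distribution("custom", sampler = function(n) matrix(0, 2, n)),
    8, seed = 1)
  st <- network_state(zero_dec, 2)
  st$weights <- matrix(rnorm(16), 8, 2)
  spec <- learning_spec(rule = "node_perturbation", perturbation_sd = 0.1)
  s2 <- node_perturbation_step(st, c(1, 0), c(1, 1), 0, spec)
  expect_equal(s2$weights, st$weights)
})

test_that("node perturbation has lower per-trial error variance than weight perturbation", {
  inst <- random_instance("linear", 13)
  st <- inst$state
  next_err <- function(rule) {
    spec <- learning_spec(learning_rate = 0.1, rule = rule,
                          perturbation_sd = 0.01)
    vapply(1:500, function(k) {
      s2 <- if (rule == "weight_perturbation") {
        weight_perturbation_step(st, inst$x, inst$tgt, inst$phi, spec)
      } else {
        node_perturbation_step(st, inst$x, inst$tgt, inst$phi, spec)
      }
      forward(s2, inst$x, inst$tgt, inst$phi)$squared_error
    }, numeric(1))
  }
  set.seed(21)
  v_wp <- var(next_err("weight_perturbation"))
  set.seed(21)
  v_np <- var(next_err("node_perturbation"))
  expect_lt(v_np, v_wp)
})

test_that("synaptic decay leaves an error floor; without decay the error vanishes", {
  dec <- decoder_from_angles(c(0, pi / 2, pi, 3 * pi / 2))  # lambda = 1/2, 1/2
  x <- c(1, 0); tgt <- c(1, 0)
  run <- function(decay) {
    st <- network_state(dec, 2)
    spec <- learning_spec(decay = decay)
    e <- NA
    for (t in 1:500) {
      fwd <- forward(st, x, tgt, pi / 4)
      e <- fwd$squared_error
      st <- gradient_step(st, fwd, x, pi / 4, spec)
    }
    e
  }
  expect_lt(run(0), 1e-20)
  expect_gt(run(0.05), 1e-4)
})

test_that("per-neuron activity change at matched error does not depend on N", {
  e <- c(0.2, -0.6); x <- c(1, 0)
  mean_du <- vapply(c(10, 100, 1000), function(N) {
    vals <- vapply(1:200, function(s) {
      dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), N,
                            seed = 5000 + s)
      st <- network_state(dec, 2)
      fake_fwd <- structure(list(error_vector = e, activities_det = rep(0, N),
                                 squared_error = 0.5 * sum(e^2),
                                 drives = NULL, phi = 0),
                            class = "forward_result")
      s2 <- gradient_step(st, fake_fwd, x, 0, learning_spec())
      mean(abs((s2$weights - st$weights) %*% x))
    }, numeric(1))
    mean(vals)
  }, numeric(1))
  expect_true(max(mean_du) / min(mean_du) < 1.05)
})
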