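#' Decoder (force-vector) distributions
#'
#' The decoder maps N neural activities to M output forces; its i-th column
#' is neuron i's force vector, with angle = force direction (FD) and norm =
#' force amplitude (FA). Supported sampling families:
#'
#' * `homogeneous_uniform`: unit-norm force vectors with FD uniform on
#'   `[0, 2*pi)` (the fixed homogeneous decoder).
#' * `gaussian_unimodal`: force vectors drawn from one 2-D Gaussian.
#' * `gaussian_bimodal`: mixture of two 2-D Gaussians (by default mirrored
#'   through the origin).
#' * `gaussian_highdim`: i.i.d. standard-normal entries, `n_outputs` rows,
#'   scaled by `1/sqrt(N)` -- used for the high-dimensional task sets where
#'   redundancy is the gap between N and the task count T.
#' * `custom`: user-supplied `sampler(n)` returning an M x n matrix.
#'
#' The Gaussian defaults are calibrated so the population second moment
#' `E[d d^T]` equals `I/2` exactly -- the same operator as the homogeneous
#' family -- while the FD histogram is unimodal (single mean) or clearly
#' bimodal (mirrored means) and the FA histogram is right-skewed. This is
#' the regime in which non-uniform tuning distributions still satisfy the
#' second-moment (self-averaging) conditions that maximize learning speed.
#'
#' @param family one of the families above.
#' @param mean,cov unimodal family: 2-vector mean and 2 x 2 SPD covariance.
#' @param means,covs bimodal family: list of two means and two SPD
#'   covariances.
#' @param weight bimodal mixture weight of the first component.
#' @param n_outputs output dimension M (2 except for `gaussian_highdim`).
#' @param sampler for `family = "custom"`: `function(n)` returning an
#'   `n_outputs x n` matrix of raw force vectors.
#' @return an object of class `"decoder_distribution"`.
#' @export
decoder_distribution <- function(family = c("homogeneous_uniform",
                                            "gaussian_unimodal",
                                            "gaussian_bimodal",
                                            "gaussian_highdim", "custom"),
                                 mean = c(0.65, 0),
                                 cov = diag(c(0.5 - 0.65^2, 0.5)),
                                 means = list(c(0.65, 0), c(-0.65, 0)),
                                 covs = list(diag(c(0.5 - 0.65^2, 0.5)),
                                             diag(c(0.5 - 0.65^2, 0.5))),
                                 weight = 0.5,
                                 n_outputs = 2L,
                                 sampler = NULL) {
  family <- match.arg(family)
  check_scalar(n_outputs, "n_outputs", positive = TRUE, integerish = TRUE)
  check_spd <- function(S, name) {
    if (!is.matrix(S) || nrow(S) != 2L || ncol(S) != 2L ||
        max(abs(S - t(S))) > 1e-10 ||
        min(eigen(S, symmetric = TRUE, only.values = TRUE)$values) <= 0) {
      stop_invalid("`%s` must be a symmetric positive-definite 2x2 matrix",
                   name)
    }
  }
  params <- switch(family,
    homogeneous_uniform = list(),
    gaussian_unimodal = {
      stopifnot(length(mean) == 2L)
      check_spd(cov, "cov")
      list(mean = as.numeric(mean), cov = cov)
    },
    gaussian_bimodal = {
      stopifnot(length(means) == 2L, length(covs) == 2L,
                weight > 0, weight < 1)
      check_spd(covs[[1L]], "covs[[1]]")
      check_spd(covs[[2L]], "covs[[2]]")
      list(means = lapply(means, as.numeric), covs = covs, weight = weight)
    },
    gaussian_highdim = list(n_outputs = as.integer(n_outputs)),
    custom = {
      if (!is.function(sampler)) stop_invalid("custom family needs `sampler`")
      list(sampler = sampler, n_outputs = as.integer(n_outputs))
    })
  structure(list(family = family, params = params,
                 n_outputs = if (family == "gaussian_highdim")
                   as.integer(n_outputs) else 2L),
            class = "decoder_distribution")
}

# draw n samples from a 2-D Gaussian, columns
rmvnorm2 <- function(n, mean, cov) {
  L <- chol(cov)                         # cov = t(L) %*% L
  t(L) %*% matrix(rnorm(2L * n), 2L, n) + mean
}

#' Sample a decoder matrix
#'
#' Draws N force vectors from `dist` and assembles the decoder. Raw force
#' vectors are kept alongside the scaled decoder matrix: the matrix is
#' `raw / N` for the 2-output families (so the learning operator's trace
#' does not grow with N) and `raw / sqrt(N)` for `gaussian_highdim`.
#'
#' @param dist a [decoder_distribution()].
#' @param n_neurons number of neurons N (>= 1).
#' @param seed optional integer; the same `(dist, n_neurons, seed)` always
#'   reproduces the same sample. `NULL` draws from the ambient RNG stream.
#' @return an object of class `"decoder_sample"` with fields `matrix`
#'   (M x N decoder D), `raw` (M x N unscaled force vectors), `n_neurons`,
#'   `n_outputs`, `family`, `scaling` (`"inv_n"` or `"inv_sqrt_n"`) and
#'   `seed`.
#' @export
#' @examples
#' dec <- sample_decoder(decoder_distribution("homogeneous_uniform"), 100, seed = 1)
#' colSums(dec$raw^2)[1:5]   # unit-norm force vectors
sample_decoder <- function(dist, n_neurons, seed = NULL) {
  stopifnot(inherits(dist, "decoder_distribution"))
  check_scalar(n_neurons, "n_neurons", positive = TRUE, integerish = TRUE)
  N <- as.integer(n_neurons)
  raw <- with_seed(seed, switch(dist$family,
    homogeneous_uniform = {
      psi <- runif(N, 0, 2 * pi)
      rbind(cos(psi), sin(psi))
    },
    gaussian_unimodal = rmvnorm2(N, dist$params$mean, dist$params$cov),
    gaussian_bimodal = {
      p <- dist$params
      comp <- runif(N) < p$weight
      out <- matrix(0, 2L, N)
      if (any(comp)) out[, comp] <- rmvnorm2(sum(comp), p$means[[1L]],
                                             p$covs[[1L]])
      if (any(!comp)) out[, !comp] <- rmvnorm2(sum(!comp), p$means[[2L]],
                                               p$covs[[2L]])
      out
    },
    gaussian_highdim = matrix(rnorm(dist$n_outputs * N), dist$n_outputs, N),
    custom = {
      out <- dist$params$sampler(N)
      stopifnot(is.matrix(out), ncol(out) == N)
      out
    }))
  scaling <- if (dist$family == "gaussian_highdim") "inv_sqrt_n" else "inv_n"
  mat <- if (scaling == "inv_n") raw / N else raw / sqrt(N)
  structure(list(matrix = mat, raw = raw, n_neurons = N,
                 n_outputs = nrow(raw), family = dist$family,
                 scaling = scaling,
                 seed = if (is.null(seed)) NA_integer_ else as.integer(seed)),
            class = "decoder_sample")
}

#' @export
print.decoder_sample <- function(x, ...) {
  cat(sprintf("Decoder sample: %d neurons -> %d outputs (%s, %s scaling)\n",
              x$n_neurons, x$n_outputs, x$family, x$scaling))
  invisible(x)
}

#' Learning operator A of a decoder sample
#'
#' `A = (1/N) * sum_i d_i d_i^T` over the raw force vectors: the M x M
#' symmetric positive semi-definite operator whose eigenvalues set the
#' per-mode error contraction `(1 - eta * lambda_k)^2` under gradient
#' learning. For unit-norm force vectors `trace(A) = 1`, so the smaller
#' eigenvalue is at most 1/2 with equality iff A = I/2 (isotropy).
#'
#' @param dec a [decoder_sample()].
#' @return an M x M symmetric matrix.
#' @export
build_A <- function(dec) {
  stopifnot(inherits(dec, "decoder_sample"))
  A <- tcrossprod(dec$raw) / dec$n_neurons
  (A + t(A)) / 2
}

#' Closed-form eigensystem of a symmetric 2 x 2 matrix
#'
#' Quadratic-formula eigenvalues (lambda1 >= lambda2) and orthonormal
#' eigenvectors, avoiding a general numeric solver for the operator the
#' theory works with.
#'
#' @param A symmetric (within 1e-10) 2 x 2 matrix.
#' @return list with `values` (decreasing) and `vectors` (columns,
#'   orthonormal) satisfying `A = V diag(values) V^T`.
#' @export
eigensystem_2x2 <- function(A) {
  if (!is.matrix(A) || any(dim(A) != 2L)) stop_invalid("`A` must be 2x2")
  if (max(abs(A - t(A))) > 1e-10) stop_invalid("`A` must be symmetric")
  a <- A[1L, 1L]; b <- A[1L, 2L]; d <- A[2L, 2L]
  mid <- (a + d) / 2
  disc <- sqrt(max(((a - d) / 2)^2 + b^2, 0))
  values <- c(mid + disc, mid - disc)
  if (disc < .Machine$double.eps * max(1, abs(mid))) {
    vectors <- diag(2L)
  } else if (abs(b) < .Machine$double.eps * max(1, abs(mid))) {
    # already diagonal: order the axes by the diagonal entries
    vectors <- if (a >= d) diag(2L) else matrix(c(0, 1, -1, 0), 2L)
  } else if (abs(b) >= abs(values[1L] - a)) {
    v1 <- c(b, values[1L] - a)
    v1 <- v1 / sqrt(sum(v1^2))
    vectors <- cbind(v1, c(-v1[2L], v1[1L]))
  } else {
    v1 <- c(values[1L] - d, b)
    v1 <- v1 / sqrt(sum(v1^2))
    vectors <- cbind(v1, c(-v1[2L], v1[1L]))
  }
  dimnames(vectors) <- NULL
  list(values = values, vectors = vectors)
}

#' Self-averaging residual of a decoder sample
#'
#' Measures how far the empirical second moments of the sampled force
#' vectors are from isotropy, as the normalized spectral gap of the
#' learning operator: `(lambda1 - lambda2) / (2 * trace(A))`. It is zero
#' iff the empirical second-moment conditions hold exactly (equal marginal
#' second moments and zero cross moment in every basis), and equals 1/2
#' for a single neuron (maximal anisotropy: rank-1 operator). For uniform
#' sampling the residual shrinks as `N^(-1/2)`, the Monte-Carlo
#' fluctuation rate, which is the self-averaging route by which redundancy
#' maximizes the smaller eigenvalue.
#'
#' @param dec a [decoder_sample()] with 2 outputs.
#' @return non-negative scalar in `[0, 1/2]`.
#' @export
self_averaging_residual <- function(dec) {
  stopifnot(inherits(dec, "decoder_sample"))
  if (dec$n_outputs != 2L) stop_invalid("requires a 2-output decoder")
  A <- build_A(dec)
  ev <- eigensystem_2x2(A)$values
  (ev[1L] - ev[2L]) / (2 * sum(diag(A)))
}

#' Preferred directions and modulation depths of tuned neurons
#'
#' Under 2-D cosine input encoding, neuron i's activity is
#' `w_i . (cos theta, sin theta)`: its preferred direction (PD) is the
#' planar angle of weight row `w_i` and its modulation depth the row norm.
#' Applied to post-baseline weights this recovers the tuning histograms
#' implied by the decoder distribution (gradient learning from zero
#' weights drives each row along its neuron's force-vector image).
#'
#' @param weights N x 2 matrix of input weights (cosine2d encoding).
#' @return an object of class `"tuning_summary"`: list with
#'   `preferred_dirs` (angles in `[-pi, pi)`) and `modulation_depths`
#'   (non-negative).
#' @export
tuning_summary <- function(weights) {
  if (!is.matrix(weights) || ncol(weights) != 2L) {
    stop_invalid("tuning summaries require an N x 2 weight matrix (cosine2d encoding)")
  }
  pd <- atan2(weights[, 2L], weights[, 1L])
  pd[pd >= pi] <- pd[pd >= pi] - 2 * pi
  structure(list(preferred_dirs = pd,
                 modulation_depths = sqrt(rowSums(weights^2))),
            class = "tuning_summary")
}

#' Export / import decoder samples as CSV
#'
#' One row per neuron with the raw force-vector components plus family and
#' seed metadata columns, for fixture reuse across runs.
#'
#' @param dec a [decoder_sample()].
#' @param file path to a CSV file.
#' @return `write_decoder_csv` returns `file` invisibly;
#'   `read_decoder_csv` returns a `"decoder_sample"`.
#' @export
write_decoder_csv <- function(dec, file) {
  stopifnot(inherits(dec, "decoder_sample"))
  df <- data.frame(neuron = seq_len(dec$n_neurons), t(dec$raw))
  names(df)[-1L] <- paste0("raw_", seq_len(dec$n_outputs))
  df$family <- dec$family
  df$scaling <- dec$scaling
  df$seed <- dec$seed
  write.csv(df, file, row.names = FALSE)
  invisible(file)
}

#' @rdname write_decoder_csv
#' @export
read_decoder_csv <- function(file) {
  df <- read.csv(file)
  raw_cols <- grep("^raw_", names(df))
  raw <- t(as.matrix(df[, raw_cols, drop = FALSE]))
  N <- ncol(raw)
  scaling <- as.character(df$scaling[1L])
  mat <- if (scaling == "inv_n") raw / N else raw / sqrt(N)
  dimnames(raw) <- dimnames(mat) <- NULL
  structure(list(matrix = mat, raw = raw, n_neurons = N,
                 n_outputs = nrow(raw), family = as.character(df$family[1L]),
                 scaling = scaling, seed = df$seed[1L]),
            class = "decoder_sample")
}
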