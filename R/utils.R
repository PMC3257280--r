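# Internal helpers shared across modules.

# Evaluate `code` under a temporary RNG state seeded with `seed`,
# restoring the caller's stream afterwards. seed = NULL means "use the
# ambient stream" (no save/restore), which lets outer with_seed() calls
# drive all randomness of nested sampling functions.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      set.seed(NULL)
    }
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
    set.seed(as.integer(seed))
  }
  code
}

stop_invalid <- function(...) stop(sprintf(...), call. = FALSE)

check_scalar <- function(x, name, finite = TRUE, positive = FALSE,
                         nonnegative = FALSE, integerish = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || (finite && !is.finite(x))) {
    stop_invalid("`%s` must be a single finite number", name)
  }
  if (positive && x <= 0) stop_invalid("`%s` must be positive", name)
  if (nonnegative && x < 0) stop_invalid("`%s` must be non-negative", name)
  if (integerish && abs(x - round(x)) > 1e-8) {
    stop_invalid("`%s` must be an integer", name)
  }
  invisible(x)
}

check_angle <- function(x, name) {
  if (!is.numeric(x) || any(!is.finite(x))) {
    stop_invalid("`%s` must be finite (radians)", name)
  }
  invisible(x)
}

# Spectral radius used to validate recurrent weight matrices.
spectral_radius <- function(K) max(Mod(eigen(K, only.values = TRUE)$values))

is_verbose <- function() isTRUE(getOption("redmotor.verbose", FALSE))

log_step <- function(rule, trial, err, dw_norm) {
  if (is_verbose()) {
    message(sprintf("trial=%d rule=%s E=%.6g |dW|=%.6g",
                    trial, rule, err, dw_norm))
  }
}

# Parse an angle given either in radians (plain number) or with an
# explicit "deg" suffix, e.g. "45deg".
parse_angle <- function(x) {
  if (is.numeric(x)) return(as.numeric(x))
  x <- trimws(as.character(x))
  if (grepl("deg$", x)) {
    as.numeric(sub("deg$", "", x)) * pi / 180
  } else {
    as.numeric(x)
  }
}
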