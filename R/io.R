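# Plain-text serialization: "key: value" config files for task and
# encoding specs, CSV snapshots for network state matrices. Angles are
# written in radians; a "deg" suffix is accepted on read.

#' Write a task or encoding spec to a plain-text config file
#'
#' One `key: value` line per field, with a leading `type:` line naming the
#' object class. Angles are written in radians.
#'
#' @param x a [task_spec()] or [input_encoding()].
#' @param file output path.
#' @return `file`, invisibly.
#' @export
write_config <- function(x, file) {
  if (inherits(x, "task_spec")) {
    lines <- c("type: task_spec",
               sprintf("n_targets: %d", x$n_targets),
               sprintf("target_radius: %.17g", x$target_radius),
               sprintf("rotation_angle: %.17g", x$rotation_angle),
               sprintf("n_baseline_trials: %d", x$n_baseline_trials),
               sprintf("n_learning_trials: %d", x$n_learning_trials),
               sprintf("target_sequence_seed: %d", x$target_sequence_seed))
  } else if (inherits(x, "input_encoding")) {
    lines <- c("type: input_encoding",
               sprintf("kind: %s", x$kind),
               sprintf("n_units: %d", x$n_units),
               sprintf("kappa: %.17g", x$kappa))
  } else {
    stop_invalid("write_config() supports task_spec and input_encoding")
  }
  writeLines(lines, file)
  invisible(file)
}

#' Read a config file written by [write_config()]
#'
#' Angle values may carry a `"deg"` suffix (e.g. `rotation_angle: 45deg`).
#'
#' @param file path to a config file.
#' @return a [task_spec()] or [input_encoding()] according to the file's
#'   `type:` line.
#' @export
read_config <- function(file) {
  lines <- readLines(file)
  lines <- lines[nzchar(trimws(lines))]
  kv <- strsplit(lines, ":", fixed = TRUE)
  keys <- vapply(kv, function(p) trimws(p[[1L]]), character(1))
  vals <- vapply(kv, function(p) trimws(paste(p[-1L], collapse = ":")),
                 character(1))
  rec <- setNames(as.list(vals), keys)
  type <- rec$type
  if (is.null(type)) stop_invalid("config file has no `type:` line")
  if (type == "task_spec") {
    task_spec(n_targets = as.integer(rec$n_targets),
              target_radius = as.numeric(rec$target_radius),
              rotation_angle = parse_angle(rec$rotation_angle),
              n_baseline_trials = as.integer(rec$n_baseline_trials),
              n_learning_trials = as.integer(rec$n_learning_trials),
              target_sequence_seed = as.integer(rec$target_sequence_seed))
  } else if (type == "input_encoding") {
    if (rec$kind == "cosine2d") input_encoding("cosine2d")
    else input_encoding("von_mises", n_units = as.integer(rec$n_units),
                        kappa = as.numeric(rec$kappa))
  } else {
    stop_invalid("unknown config type `%s`", type)
  }
}

#' Snapshot a network state to a directory of CSV files
#'
#' Writes `weights.csv`, `decoder.csv` (via [write_decoder_csv()]),
#' optionally `recurrent.csv` and `muscle.csv`, and a `meta` config with
#' the scalar fields -- a portable checkpoint for restart tests.
#'
#' @param state a [network_state()].
#' @param dir target directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_network_state <- function(state, dir) {
  stopifnot(inherits(state, "network_state"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write.csv(state$weights, file.path(dir, "weights.csv"), row.names = FALSE)
  write_decoder_csv(state$decoder, file.path(dir, "decoder.csv"))
  if (!is.null(state$recurrent)) {
    write.csv(state$recurrent, file.path(dir, "recurrent.csv"),
              row.names = FALSE)
  }
  if (!is.null(state$muscle)) {
    write.csv(state$muscle$matrix, file.path(dir, "muscle.csv"),
              row.names = FALSE)
    writeLines(sprintf("%.17g", state$muscle$pull_dirs),
               file.path(dir, "muscle_pull_dirs.txt"))
  }
  meta <- c(sprintf("activation: %s", state$activation),
            sprintf("adaptable_decoder: %s", state$adaptable_decoder),
            sprintf("trial_index: %d", state$trial_index))
  if (!is.null(state$muscle)) {
    tone <- if (is.null(state$muscle$tone)) 0 else state$muscle$tone
    meta <- c(meta, sprintf("muscle_tone: %.17g", tone))
  }
  writeLines(meta, file.path(dir, "meta.txt"))
  invisible(dir)
}

#' Restore a network state written by [write_network_state()]
#'
#' @param dir snapshot directory.
#' @return a [network_state()].
#' @export
read_network_state <- function(dir) {
  dec <- read_decoder_csv(file.path(dir, "decoder.csv"))
  W <- as.matrix(read.csv(file.path(dir, "weights.csv")))
  dimnames(W) <- NULL
  recurrent <- NULL
  if (file.exists(file.path(dir, "recurrent.csv"))) {
    recurrent <- as.matrix(read.csv(file.path(dir, "recurrent.csv")))
    dimnames(recurrent) <- NULL
  }
  meta <- readLines(file.path(dir, "meta.txt"))
  get_meta <- function(key) {
    line <- grep(paste0("^", key, ":"), meta, value = TRUE)
    trimws(sub("^[^:]+:", "", line))
  }
  muscle <- NULL
  if (file.exists(file.path(dir, "muscle.csv"))) {
    mm <- as.matrix(read.csv(file.path(dir, "muscle.csv")))
    dimnames(mm) <- NULL
    muscle <- list(matrix = mm,
                   pull_dirs = as.numeric(readLines(
                     file.path(dir, "muscle_pull_dirs.txt"))),
                   tone = as.numeric(get_meta("muscle_tone")))
  }
  state <- network_state(dec, input_dim = ncol(W),
                         activation = get_meta("activation"),
                         recurrent = recurrent, muscle = muscle,
                         adaptable_decoder =
                           as.logical(get_meta("adaptable_decoder")))
  state$weights <- W
  state$trial_index <- as.integer(get_meta("trial_index"))
  state
}
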