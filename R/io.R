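# File round-tripping: TSV trial tables and split assignments, TSV + JSON
# containers for epochs / waveforms / recordings / leadfields, YAML configs
# and JSON reports.  Array payloads use a plain-text layout (a TSV body with
# a JSON metadata sidecar) so every artifact stays human-auditable; all
# containers are schema_version-stamped and checked on read.

TRIAL_COLUMNS <- c("subject", "task", "block", "block_in_task", "trial",
                   "uid", "onset_s", "color_pair", "target_color",
                   "probe_color", "target_orientation", "trial_type",
                   "repetition", "rt_ms", "correct")

read_meta <- function(path, expected_kind) {
  if (!file.exists(path)) stop_data("missing metadata file: ", path)
  meta <- tryCatch(jsonlite::read_json(path, simplifyVector = TRUE),
                   error = function(e) {
                     stop_data("malformed metadata in ", path, ": ",
                                 conditionMessage(e))
                   })
  if (!identical(meta$kind, expected_kind)) {
    stop_config(path, " does not describe a ", expected_kind)
  }
  if (!identical(as.character(meta$schema_version), SCHEMA_VERSION)) {
    stop_data("schema_version mismatch in ", path, ": found ",
                meta$schema_version %||% "<none>", ", expected ",
                SCHEMA_VERSION)
  }
  meta
}

write_meta <- function(meta, path, kind) {
  meta$kind <- kind
  meta$schema_version <- SCHEMA_VERSION
  jsonlite::write_json(meta, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
}

read_body <- function(path) {
  if (!file.exists(path)) stop_data("missing data file: ", path)
  tryCatch(data.table::fread(path, sep = "\t", header = TRUE,
                             na.strings = ""),
           error = function(e) {
             stop_data("failed to read ", path, ": ", conditionMessage(e))
           })
}

#' Write / read a trial table as TSV
#'
#' One row per trial, tab-separated, missing values as empty strings.  All
#' columns present are written (a superset of the core trial fields when
#' flags or coupling deviates have been added), so write-then-read is
#' lossless.
#'
#' @param trials a trial table.
#' @param path output/input TSV path.
#' @return `read_trials` returns the trial table; `write_trials` its path,
#'   invisibly.
#' @export
write_trials <- function(trials, path) {
  data.table::fwrite(trials, path, sep = "\t", na = "", quote = FALSE)
  invisible(path)
}

#' @rdname write_trials
#' @export
read_trials <- function(path) {
  dt <- read_body(path)
  missing_cols <- setdiff(TRIAL_COLUMNS, names(dt))
  if (length(missing_cols)) {
    stop_data("trial table ", path, " lacks required column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  out <- as.data.frame(dt)
  out$correct <- as.logical(out$correct)
  for (fl in intersect(c("invalid_rt", "anticipatory", "delayed", "incorrect",
                         "erp_eligible"), names(out))) {
    out[[fl]] <- as.logical(out[[fl]])
  }
  out
}

#' Write / read an epoch set
#'
#' Directory container: `epochs.tsv` holds one row per trial x channel with
#' the per-sample voltages, `epochs.json` the time axis, channel names,
#' sampling rate, trial ids and baseline flag.
#'
#' @param epochs an `epoch_set`.
#' @param dir container directory (created if needed).
#' @return `read_epochs` returns the `epoch_set`; `write_epochs` the
#'   directory, invisibly.
#' @export
write_epochs <- function(epochs, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  d <- dim(epochs$data)
  flat <- matrix(aperm(epochs$data, c(3L, 2L, 1L)), nrow = d[1] * d[2],
                 byrow = TRUE)
  body <- data.table::data.table(uid = rep(epochs$trial_ids, each = d[2]),
                                 channel = rep(epochs$channels, d[1]))
  body <- cbind(body, data.table::as.data.table(flat))
  data.table::fwrite(body, file.path(dir, "epochs.tsv"), sep = "\t")
  write_meta(list(time_ms = epochs$time_ms, channels = epochs$channels,
                  sampling_rate = epochs$sampling_rate,
                  trial_ids = epochs$trial_ids,
                  baseline_applied = epochs$baseline_applied),
             file.path(dir, "epochs.json"), kind = "epoch_set")
  invisible(dir)
}

#' @rdname write_epochs
#' @export
read_epochs <- function(dir) {
  meta <- read_meta(file.path(dir, "epochs.json"), "epoch_set")
  body <- read_body(file.path(dir, "epochs.tsv"))
  nch <- length(meta$channels)
  ntr <- length(meta$trial_ids)
  ns <- length(meta$time_ms)
  if (nrow(body) != ntr * nch) {
    stop_data("epoch container is corrupt: expected ", ntr * nch,
                " rows, found ", nrow(body))
  }
  flat <- as.matrix(body[, -(1:2)])
  if (ncol(flat) != ns) stop_data("epoch container is corrupt: wrong sample count")
  data <- aperm(array(t(flat), dim = c(ns, nch, ntr)), c(3L, 2L, 1L))
  new_epoch_set(data, meta$time_ms, meta$channels, meta$sampling_rate,
                meta$trial_ids, meta$baseline_applied)
}

#' Write / read a waveform
#'
#' TSV with a `time_ms` column plus one column per channel; metadata
#' (sampling rate, trial counts, label) in a JSON sidecar `<path>.json`.
#'
#' @param w a `waveform`.
#' @param path TSV path.
#' @return `read_waveform` returns the `waveform`; `write_waveform` its
#'   path, invisibly.
#' @export
write_waveform <- function(w, path) {
  body <- data.table::data.table(time_ms = w$time_ms)
  for (i in seq_along(w$channels)) body[[w$channels[i]]] <- w$data[i, ]
  data.table::fwrite(body, path, sep = "\t")
  write_meta(list(channels = w$channels, sampling_rate = w$sampling_rate,
                  n_trials = w$n_trials, label = w$label),
             paste0(path, ".json"), kind = "waveform")
  invisible(path)
}

#' @rdname write_waveform
#' @export
read_waveform <- function(path) {
  meta <- read_meta(paste0(path, ".json"), "waveform")
  body <- read_body(path)
  missing_cols <- setdiff(c("time_ms", meta$channels), names(body))
  if (length(missing_cols)) {
    stop_data("waveform ", path, " lacks column(s): ",
                paste(missing_cols, collapse = ", "))
  }
  data <- t(as.matrix(body[, meta$channels, with = FALSE]))
  new_waveform(data, body$time_ms, meta$channels, meta$sampling_rate,
               n_trials = unlist(meta$n_trials),
               label = as.list(meta$label))
}

#' Write / read a continuous recording
#'
#' Directory container: `recording.tsv` (one row per channel),
#' `events.tsv` (0-based sample index and trial uid) and `recording.json`.
#'
#' @param recording a `continuous_recording`.
#' @param dir container directory.
#' @return `read_recording` returns the recording; `write_recording` the
#'   directory, invisibly.
#' @export
write_recording <- function(recording, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  body <- data.table::data.table(channel = recording$channels)
  body <- cbind(body, data.table::as.data.table(recording$data))
  data.table::fwrite(body, file.path(dir, "recording.tsv"), sep = "\t")
  data.table::fwrite(recording$events, file.path(dir, "events.tsv"),
                     sep = "\t")
  write_meta(list(channels = recording$channels,
                  sampling_rate = recording$sampling_rate),
             file.path(dir, "recording.json"), kind = "continuous_recording")
  invisible(dir)
}

#' @rdname write_recording
#' @export
read_recording <- function(dir) {
  meta <- read_meta(file.path(dir, "recording.json"), "continuous_recording")
  body <- read_body(file.path(dir, "recording.tsv"))
  events <- as.data.frame(read_body(file.path(dir, "events.tsv")))
  if (!identical(body$channel, meta$channels)) {
    stop_data("recording container is corrupt: channel mismatch")
  }
  data <- as.matrix(body[, -1])
  rownames(data) <- meta$channels
  structure(list(data = data, channels = meta$channels,
                 sampling_rate = meta$sampling_rate, events = events),
            class = "continuous_recording")
}

#' Write / read a leadfield
#'
#' Directory container: `gain.tsv` (sensors x sources), `locations.tsv`
#' (3D source coordinates in mm) and `leadfield.json`.
#'
#' @param L a `leadfield`.
#' @param dir container directory.
#' @return `read_leadfield` returns the `leadfield`; `write_leadfield` the
#'   directory, invisibly.
#' @export
write_leadfield <- function(L, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  data.table::fwrite(data.table::as.data.table(L$gain),
                     file.path(dir, "gain.tsv"), sep = "\t")
  data.table::fwrite(data.table::as.data.table(L$locations),
                     file.path(dir, "locations.tsv"), sep = "\t")
  write_meta(list(sensors = L$sensors), file.path(dir, "leadfield.json"),
             kind = "leadfield")
  invisible(dir)
}

#' @rdname write_leadfield
#' @export
read_leadfield <- function(dir) {
  meta <- read_meta(file.path(dir, "leadfield.json"), "leadfield")
  gain <- as.matrix(read_body(file.path(dir, "gain.tsv")))
  loc <- as.matrix(read_body(file.path(dir, "locations.tsv")))
  dimnames(gain) <- NULL
  new_leadfield(gain, meta$sensors, loc)
}

#' Write / read a pipeline configuration as YAML
#'
#' The YAML mirrors the [pipeline_config()] structure; unknown keys are
#' rejected on read and every block is re-validated.
#'
#' @param config a `pipeline_config`.
#' @param path YAML path.
#' @return `read_config` returns the validated `pipeline_config`;
#'   `write_config` the path, invisibly.
#' @export
write_config <- function(config, path) {
  if (!inherits(config, "pipeline_config")) {
    stop_config("'config' must be a pipeline_config")
  }
  plain <- lapply(unclass(config), function(x) if (is.list(x)) unclass(x) else x)
  # named vectors must become mappings, not plain sequences
  plain$paradigm$mastoid_channels <- as.list(config$paradigm$mastoid_channels)
  yaml::write_yaml(plain, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop_config("config file not found: ", path)
  raw <- tryCatch(yaml::read_yaml(path), error = function(e) {
    stop_data("malformed YAML in ", path, ": ", conditionMessage(e))
  })
  known <- c("schema_version", "paradigm", "effects", "preprocessing",
             "stats", "splits", "source", "seed")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop_config("unknown configuration block(s): ", paste(extra, collapse = ", "))
  }
  build <- function(fn, block, what) {
    block <- block %||% list()
    extra <- setdiff(names(block), names(formals(fn)))
    if (length(extra)) {
      stop_config("unknown ", what, " option(s): ", paste(extra, collapse = ", "))
    }
    if (what == "paradigm" && !is.null(block$mastoid_channels)) {
      block$mastoid_channels <- unlist(block$mastoid_channels)
    }
    do.call(fn, block)
  }
  pipeline_config(paradigm = build(paradigm_config, raw$paradigm, "paradigm"),
                  effects = build(effect_params, raw$effects, "effects"),
                  preprocessing = raw$preprocessing %||% list(),
                  stats = raw$stats %||% list(),
                  splits = raw$splits %||% list(),
                  source = raw$source %||% list(),
                  seed = raw$seed %||% 1L)
}

#' Write a machine-readable run report
#'
#' @param report a report list (see [run_pipeline()]).
#' @param path JSON path.
#' @return The path, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(report, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, na = "null")
  invisible(path)
}

#' Write a split assignment as TSV
#'
#' @param assignment a split assignment table (subject, uid, split, tag).
#' @param path TSV path.
#' @return The path, invisibly.
#' @export
write_split_assignment <- function(assignment, path) {
  data.table::fwrite(assignment, path, sep = "\t")
  invisible(path)
}
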