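#' Sensor specification
#'
#' Describes one tri-axial sensor in a SisFall-style raw file: its full-scale
#' range and ADC resolution. Raw integer readings `r` are converted to
#' physical units by the linear map `r * 2 * range / 2^resolution_bits`, so a
#' reading of `2^(resolution_bits - 1)` corresponds to full scale.
#'
#' @param name Identifier, e.g. `"ADXL345"`.
#' @param range Full-scale range, in g for accelerometers or deg/s for
#'   gyroscopes. Must be positive.
#' @param resolution_bits ADC resolution, an integer in 8..16.
#' @param unit Physical unit label, `"g"` or `"deg/s"`.
#' @return An object of class `sensor_spec`.
#' @export
sensor_spec <- function(name, range, resolution_bits, unit = "g") {
  if (!is.numeric(range) || length(range) != 1L || range <= 0) {
    stop("sensor_spec: `range` must be a positive scalar", call. = FALSE)
  }
  resolution_bits <- as.integer(resolution_bits)
  if (is.na(resolution_bits) || resolution_bits < 8L || resolution_bits > 16L) {
    stop("sensor_spec: `resolution_bits` must be an integer in 8..16", call. = FALSE)
  }
  structure(
    list(name = as.character(name), range = as.numeric(range),
         resolution_bits = resolution_bits, axes = 3L, unit = unit),
    class = "sensor_spec"
  )
}

#' @export
print.sensor_spec <- function(x, ...) {
  cat(sprintf("<sensor_spec> %s: +/-%g %s, %d-bit (scale %.6g %s/LSB)\n",
              x$name, x$range, x$unit, x$resolution_bits, sensor_scale(x), x$unit))
  invisible(x)
}

#' Physical units per ADC count for a sensor
#'
#' @param spec A [sensor_spec()].
#' @return Scalar scale factor `2 * range / 2^resolution_bits`.
#' @export
sensor_scale <- function(spec) {
  2 * spec$range / 2^spec$resolution_bits
}

#' Default SisFall sensor schema
#'
#' The SisFall recording unit carries three tri-axial sensors per line, in
#' this column order: a wide-range accelerometer (+/-16 g, 13-bit), a
#' gyroscope (+/-2000 deg/s, 16-bit) and a second, low-range accelerometer
#' (+/-8 g, 14-bit). The schema (names, ranges, resolutions) is read from a
#' YAML config so that simulator-generated cohorts can declare their own.
#'
#' @param path YAML file describing the sensors; defaults to the schema
#'   shipped with the package.
#' @return A list of [sensor_spec()] objects, one per tri-axial sensor.
#' @export
sisfall_sensor_schema <- function(path = system.file("extdata", "sisfall_sensors.yaml",
                                                     package = "fallnet")) {
  cfg <- yaml::read_yaml(path)
  lapply(cfg$sensors, function(s) {
    sensor_spec(s$name, s$range, s$resolution_bits, unit = s$unit)
  })
}

schema_n_channels <- function(schema) {
  sum(vapply(schema, function(s) s$axes, integer(1)))
}

schema_scales <- function(schema) {
  unlist(lapply(schema, function(s) rep(sensor_scale(s), s$axes)))
}

schema_colnames <- function(schema) {
  unlist(lapply(schema, function(s) paste0(s$name, "_", c("x", "y", "z"))))
}

#' Construct a recording trial
#'
#' A trial is a multichannel inertial time series in physical units (g for
#' acceleration, deg/s for angular velocity) plus the metadata encoded in a
#' SisFall filename.
#'
#' @param samples Numeric matrix, T samples x C channels.
#' @param rate_hz Sampling frequency in Hz (SisFall uses 200).
#' @param subject_id Subject identifier, e.g. `"SA01"` or `"SE03"`.
#' @param subject_group `"young"` or `"elderly"`.
#' @param activity_code Activity identifier, e.g. `"D02"` (ADL) or `"F01"` (fall).
#' @param trial_index Trial repetition number within subject x activity.
#' @param is_fall_activity Whether the activity is a fall type.
#' @return An object of class `recording_trial`.
#' @export
recording_trial <- function(samples, rate_hz = 200, subject_id = "S00",
                            subject_group = c("young", "elderly"),
                            activity_code = "D00", trial_index = 1L,
                            is_fall_activity = startsWith(activity_code, "F")) {
  samples <- as.matrix(samples)
  storage.mode(samples) <- "double"
  if (nrow(samples) < 1L) stop("recording_trial: needs at least one sample", call. = FALSE)
  if (anyNA(samples)) stop("recording_trial: missing samples are not allowed", call. = FALSE)
  if (!is.numeric(rate_hz) || rate_hz <= 0) {
    stop("recording_trial: `rate_hz` must be positive", call. = FALSE)
  }
  structure(
    list(samples = samples, rate_hz = as.numeric(rate_hz),
         subject_id = as.character(subject_id),
         subject_group = match.arg(subject_group),
         activity_code = as.character(activity_code),
         trial_index = as.integer(trial_index),
         is_fall_activity = isTRUE(is_fall_activity)),
    class = "recording_trial"
  )
}

#' @export
print.recording_trial <- function(x, ...) {
  cat(sprintf("<recording_trial> %s %s R%02d: %d samples x %d channels @ %g Hz (%s, %s)\n",
              x$activity_code, x$subject_id, x$trial_index,
              nrow(x$samples), ncol(x$samples), x$rate_hz, x$subject_group,
              if (x$is_fall_activity) "fall" else "ADL"))
  invisible(x)
}

#' @export
dim.recording_trial <- function(x) dim(x$samples)

# Filename dialect: <ACT>_<SUBJ>_R<trial>.txt, e.g. F01_SE06_R02.txt
parse_trial_filename <- function(path) {
  base <- sub("\\.txt$", "", basename(path))
  m <- regmatches(base, regexec("^([A-Z][0-9]+)_((SA|SE)[0-9]+)_R([0-9]+)$", base))[[1]]
  if (length(m) == 0L) {
    stop(sprintf("cannot parse trial metadata from filename '%s' (expected <ACT>_<SUBJ>_R<trial>.txt)",
                 basename(path)), call. = FALSE)
  }
  list(activity_code = m[2], subject_id = m[3],
       subject_group = if (m[4] == "SE") "elderly" else "young",
       trial_index = as.integer(m[5]),
       is_fall_activity = startsWith(m[2], "F"))
}

trial_filename <- function(trial) {
  sprintf("%s_%s_R%02d.txt", trial$activity_code, trial$subject_id, trial$trial_index)
}

#' Read a SisFall-style raw trial file
#'
#' Lines are comma-separated integer ADC readings, one sample per line, with
#' an optional trailing semicolon. Raw integers are converted to physical
#' units channel-wise using the linear scale of each sensor in `schema`.
#' Trial metadata (activity, subject, repetition) is parsed from the
#' filename pattern `<ACT>_<SUBJ>_R<trial>.txt`.
#'
#' @param path Path to the trial file.
#' @param schema List of [sensor_spec()]; total channel count must match the
#'   file's column count. Defaults to [sisfall_sensor_schema()].
#' @param rate_hz Sampling rate declared for the file. No resampling is
#'   performed; the value is recorded on the trial.
#' @return A [recording_trial()] in physical units.
#' @export
read_trial <- function(path, schema = sisfall_sensor_schema(), rate_hz = 200) {
  if (!file.exists(path)) stop(sprintf("trial file not found: %s", path), call. = FALSE)
  meta <- parse_trial_filename(path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) stop(sprintf("trial file is empty: %s", path), call. = FALSE)
  nc <- schema_n_channels(schema)
  parts <- strsplit(sub(";\\s*$", "", trimws(lines)), ",", fixed = TRUE)
  bad <- which(lengths(parts) != nc)
  if (length(bad) > 0L) {
    stop(sprintf("parse error in %s at line %d: expected %d comma-separated values, found %d",
                 basename(path), bad[1], nc, lengths(parts)[bad[1]]), call. = FALSE)
  }
  raw <- matrix(suppressWarnings(as.numeric(unlist(parts))),
                nrow = length(lines), ncol = nc, byrow = TRUE)
  if (anyNA(raw)) {
    bad <- which(apply(is.na(raw), 1, any))[1]
    stop(sprintf("parse error in %s at line %d: non-numeric field", basename(path), bad),
         call. = FALSE)
  }
  phys <- sweep(raw, 2, schema_scales(schema), `*`)
  colnames(phys) <- schema_colnames(schema)
  recording_trial(phys, rate_hz = rate_hz, subject_id = meta$subject_id,
                  subject_group = meta$subject_group,
                  activity_code = meta$activity_code,
                  trial_index = meta$trial_index,
                  is_fall_activity = meta$is_fall_activity)
}

#' Write a trial in the SisFall text dialect
#'
#' Physical-unit samples are quantized back to integer ADC readings with the
#' inverse of each sensor's scale (round to nearest), so a write-read
#' round trip reproduces the matrix up to half an ADC step per sample.
#'
#' @param trial A [recording_trial()] whose channel count matches `schema`.
#' @param path Output file path; the filename should follow the
#'   `<ACT>_<SUBJ>_R<trial>.txt` pattern if it is to be read back.
#' @param schema List of [sensor_spec()].
#' @return `path`, invisibly.
#' @export
write_trial <- function(trial, path, schema = sisfall_sensor_schema()) {
  nc <- schema_n_channels(schema)
  if (ncol(trial$samples) != nc) {
    stop(sprintf("write_trial: trial has %d channels but schema implies %d",
                 ncol(trial$samples), nc), call. = FALSE)
  }
  raw <- round(sweep(trial$samples, 2, schema_scales(schema), `/`))
  lines <- paste0(apply(raw, 1, paste, collapse = ","), ";")
  tryCatch(writeLines(lines, path),
           error = function(e) stop(sprintf("write_trial: cannot write %s: %s",
                                            path, conditionMessage(e)), call. = FALSE))
  invisible(path)
}

#' Select the model input channels from a raw trial
#'
#' Raw SisFall files carry 9 channels (two accelerometers + one gyroscope);
#' the classifiers consume 6: one tri-axial accelerometer followed by the
#' tri-axial gyroscope. The default takes the first (wide-range)
#' accelerometer, since fall impacts reach multi-g peaks that can clip a
#' low-range sensor.
#'
#' @param trial A [recording_trial()].
#' @param channel_spec Integer indices of the columns to keep, in
#'   accelerometer-then-gyroscope order. Default `c(1:3, 4:6)`.
#' @return The trial restricted to the requested channels; sample count and
#'   rate are unchanged.
#' @export
select_channels <- function(trial, channel_spec = 1:6) {
  channel_spec <- as.integer(channel_spec)
  if (anyNA(channel_spec) || any(channel_spec < 1L) ||
      any(channel_spec > ncol(trial$samples))) {
    stop("select_channels: channel index out of range", call. = FALSE)
  }
  if (anyDuplicated(channel_spec)) {
    stop("select_channels: duplicate channel indices", call. = FALSE)
  }
  trial$samples <- trial$samples[, channel_spec, drop = FALSE]
  trial
}

#' Read a stage-annotation sidecar CSV
#'
#' One row per trial: `trial_id, pre_impact_start, pre_impact_end, fall_end`,
#' all 0-based sample indices delimiting half-open intervals. `trial_id` is
#' the trial filename without extension.
#'
#' @param path CSV path.
#' @return Named list of [stage_annotation()] keyed by trial id.
#' @export
read_annotations <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("trial_id", "pre_impact_start", "pre_impact_end", "fall_end")
  if (!all(need %in% names(df))) {
    stop(sprintf("annotation file %s lacks columns: %s", path,
                 paste(setdiff(need, names(df)), collapse = ", ")), call. = FALSE)
  }
  ann <- lapply(seq_len(nrow(df)), function(i) {
    stage_annotation(df$pre_impact_start[i], df$pre_impact_end[i], df$fall_end[i])
  })
  names(ann) <- df$trial_id
  ann
}

#' Write a stage-annotation sidecar CSV
#'
#' @param annotations Named list of [stage_annotation()] keyed by trial id.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  df <- data.frame(
    trial_id = names(annotations),
    pre_impact_start = vapply(annotations, `[[`, numeric(1), "pre_impact_start"),
    pre_impact_end = vapply(annotations, `[[`, numeric(1), "pre_impact_end"),
    fall_end = vapply(annotations, `[[`, numeric(1), "fall_end"),
    stringsAsFactors = FALSE
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
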