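#' Synthetic IMU cohort configuration
#'
#' Describes a synthetic cohort of subjects performing ADLs and falls at
#' 200 Hz. The generated 6-channel signals (tri-axial acceleration in g,
#' tri-axial angular velocity in deg/s) follow the three-stage structure of a
#' real fall: a non-fall prefix, a descent during which acceleration
#' magnitude drops below the free-fall floor while the gyroscope spins up,
#' and an impact spike followed by settling in a changed orientation. The
#' signal model is piecewise kinematic phase templates plus per-subject
#' random effects and white Gaussian sensor noise - controllable labeled
#' structure, not biomechanical simulation.
#'
#' @param n_young,n_elderly Subject counts per group. Defaults give a
#'   desk-scale cohort of 10 subjects that trains in minutes on one CPU.
#' @param trials_per_subject Repetitions of every activity template.
#' @param fall_types List of fall templates; see [fall_templates()]. Descent
#'   duration ranges must lie within 200..800 ms (a fall lasts around
#'   800 ms).
#' @param adl_types List of ADL templates; see [adl_templates()].
#' @param rate_hz Sampling frequency; 200.
#' @param noise_sd Named vector `c(acc = , gyro = )`: white-noise SD in g and
#'   deg/s.
#' @param impact_peak_range Range of the impact acceleration-magnitude peak
#'   in g; minimum must exceed 2 g.
#' @param freefall_floor_range Range the magnitude decays to during descent,
#'   in g; maximum must stay below 0.8 g.
#' @param seed RNG seed making the whole cohort deterministic.
#' @return An object of class `sim_cohort_config`.
#' @export
sim_cohort_config <- function(n_young = 6L, n_elderly = 4L, trials_per_subject = 3L,
                              fall_types = fall_templates(),
                              adl_types = adl_templates(),
                              rate_hz = 200,
                              noise_sd = c(acc = 0.03, gyro = 3),
                              impact_peak_range = c(3, 6),
                              freefall_floor_range = c(0.1, 0.4),
                              seed = 20200212L) {
  stopifnot(n_young >= 0, n_elderly >= 0, trials_per_subject >= 0)
  if (impact_peak_range[1] <= 2) {
    stop("sim_cohort_config: impact peak minimum must exceed 2 g", call. = FALSE)
  }
  if (freefall_floor_range[2] >= 0.8) {
    stop("sim_cohort_config: free-fall floor maximum must stay below 0.8 g", call. = FALSE)
  }
  for (ft in fall_types) {
    if (ft$descent_ms[1] < 200 || ft$descent_ms[2] > 800) {
      stop(sprintf("sim_cohort_config: descent range of '%s' outside 200..800 ms", ft$name),
           call. = FALSE)
    }
  }
  structure(
    list(n_young = as.integer(n_young), n_elderly = as.integer(n_elderly),
         trials_per_subject = as.integer(trials_per_subject),
         fall_types = fall_types, adl_types = adl_types,
         rate_hz = rate_hz, noise_sd = noise_sd,
         impact_peak_range = impact_peak_range,
         freefall_floor_range = freefall_floor_range,
         seed = as.integer(seed)),
    class = "sim_cohort_config"
  )
}

#' Built-in fall templates
#'
#' Four fall directions with descent-duration ranges (ms) and the gyroscope
#' axis that carries the rotational burst. The lateral fall is the shortest,
#' the forward slip the longest. `land` is the body axis gravity ends up on.
#'
#' @return List of fall templates.
#' @export
fall_templates <- function() {
  list(
    list(name = "forward", code = "F01", descent_ms = c(500, 800),
         gyro_axis = 2L, land = c(1, 0, 0)),
    list(name = "backward", code = "F02", descent_ms = c(450, 750),
         gyro_axis = 2L, land = c(-1, 0, 0)),
    list(name = "lateral", code = "F03", descent_ms = c(250, 450),
         gyro_axis = 1L, land = c(0, 1, 0)),
    list(name = "vertical", code = "F04", descent_ms = c(300, 600),
         gyro_axis = 3L, land = c(0.35, 0, 0.937))
  )
}

#' Built-in ADL templates
#'
#' Standing (static gravity), walking and jogging (periodic gait at a
#' subject-specific cadence), and sitting down (a bounded transient well
#' below fall-impact peaks). Acceleration magnitude stays within
#' 0.5..2.5 g for every template.
#'
#' @return List of ADL templates.
#' @export
adl_templates <- function() {
  list(
    list(name = "stand", code = "D01", duration_s = c(5, 6), cadence_hz = NA, amp_g = 0),
    list(name = "walk", code = "D02", duration_s = c(5, 6), cadence_hz = 1.9, amp_g = 0.25),
    list(name = "sit", code = "D03", duration_s = c(4, 5), cadence_hz = NA, amp_g = 0),
    list(name = "jog", code = "D04", duration_s = c(5, 6), cadence_hz = 2.8, amp_g = 0.30)
  )
}

#' Draw per-subject random effects
#'
#' One draw per subject makes subject identity a real statistical unit
#' (signals within a subject are correlated through these), which is what
#' makes subject-wise splits meaningful.
#'
#' @return List with `gain` (amplitude multiplier), `cadence_factor` and
#'   `phase` (gait phase offset, radians).
#' @export
draw_subject_params <- function() {
  list(gain = stats::runif(1, 0.9, 1.1),
       cadence_factor = stats::runif(1, 0.9, 1.1),
       phase = stats::runif(1, 0, 2 * pi))
}

sim_channel_names <- function() c("ax", "ay", "az", "gx", "gy", "gz")

add_sensor_noise <- function(x, noise_sd) {
  n <- nrow(x)
  x[, 1:3] <- x[, 1:3] + matrix(stats::rnorm(3 * n, sd = noise_sd[["acc"]]), n, 3)
  x[, 4:6] <- x[, 4:6] + matrix(stats::rnorm(3 * n, sd = noise_sd[["gyro"]]), n, 3)
  x
}

# Gait-like periodic segment: vertical oscillation at the cadence plus a
# weaker second harmonic, a fore-aft component in phase, and a small
# gyroscope sway. Returns an n x 6 matrix (no noise).
gait_segment <- function(n, rate_hz, cadence_hz, amp, phase = 0) {
  t <- (seq_len(n) - 1) / rate_hz
  w <- 2 * pi * cadence_hz
  az <- 1 + amp * sin(w * t + phase) + 0.15 * amp * sin(2 * w * t + phase + 0.7)
  ax <- 0.5 * amp * sin(w * t + phase)
  ay <- 0.1 * amp * sin(w * t + phase + 1.3)
  gx <- 20 * amp / 0.25 * sin(w * t + phase + 0.4)
  gy <- 10 * amp / 0.25 * sin(w * t + phase + 2.1)
  gz <- rep(0, n)
  cbind(ax, ay, az, gx, gy, gz)
}

#' Simulate one ADL trial
#'
#' Generates a non-fall recording from a template. The annotation marks the
#' whole trial as non-fall (`pre_impact_start == pre_impact_end == fall_end
#' == T`). At zero noise the "stand" template is exactly the gravity vector
#' (|a| = 1 g), and gait templates keep acceleration magnitude within
#' 0.5..2.5 g.
#'
#' @param template One element of [adl_templates()].
#' @param subject_params From [draw_subject_params()].
#' @param config A [sim_cohort_config()] (rate and noise levels).
#' @return List with `trial` (a 6-channel [recording_trial()]) and
#'   `annotation` (a [stage_annotation()]).
#' @export
simulate_adl_trial <- function(template, subject_params = draw_subject_params(),
                               config = sim_cohort_config()) {
  rate <- config$rate_hz
  dur <- stats::runif(1, template$duration_s[1], template$duration_s[2])
  n <- round(dur * rate)
  gain <- subject_params$gain
  x <- switch(template$name,
    stand = cbind(ax = rep(0, n), ay = rep(0, n), az = rep(1, n),
                  gx = rep(0, n), gy = rep(0, n), gz = rep(0, n)),
    sit = {
      t <- (seq_len(n) - 1) / rate
      t1 <- dur * 0.4; t2 <- t1 + 0.35
      az <- 1 - 0.25 * gain * exp(-((t - t1) / 0.15)^2) +
        0.5 * gain * exp(-((t - t2) / 0.12)^2)
      gy <- 40 * gain * exp(-((t - t1 - 0.15) / 0.25)^2)
      cbind(ax = 0.1 * gain * exp(-((t - t2) / 0.2)^2), ay = rep(0, n), az = az,
            gx = rep(0, n), gy = gy, gz = rep(0, n))
    },
    gait_segment(n, rate, template$cadence_hz * subject_params$cadence_factor,
                 template$amp_g * gain, subject_params$phase)
  )
  x <- add_sensor_noise(x, config$noise_sd)
  colnames(x) <- sim_channel_names()
  trial <- recording_trial(x, rate_hz = rate, activity_code = template$code,
                           is_fall_activity = FALSE)
  list(trial = trial, annotation = stage_annotation(n, n, n))
}

#' Simulate one fall trial
#'
#' Concatenates (i) a walking prefix (non-fall), (ii) a descent whose
#' acceleration magnitude decays below the free-fall floor while a half-sine
#' angular-velocity burst (100..300 deg/s peak) builds on the template's
#' rotation axis, (iii) an impact spike with magnitude peak drawn from the
#' configured range followed by settling near 1 g in the landing
#' orientation, and (iv) a post-fall tail that the annotation excludes
#' (removed by [truncate_post_fall()]). Annotation indices coincide exactly
#' with the generative phase switches.
#'
#' @inheritParams simulate_adl_trial
#' @param template One element of [fall_templates()].
#' @return List with `trial` and `annotation` (`fall_end` strictly before the
#'   trial end: the tail is post-fall data).
#' @export
simulate_fall_trial <- function(template, subject_params = draw_subject_params(),
                                config = sim_cohort_config()) {
  rate <- config$rate_hz
  gain <- subject_params$gain

  # (i) walking prefix
  n_pre <- round(stats::runif(1, 2.5, 3.5) * rate)
  pre <- gait_segment(n_pre, rate, 1.9 * subject_params$cadence_factor,
                      0.25 * gain, subject_params$phase)

  # (ii) descent: magnitude 1 -> floor, gyro half-sine burst
  d_ms <- stats::runif(1, template$descent_ms[1], template$descent_ms[2])
  n_desc <- max(2L, round(d_ms / 1000 * rate))
  u <- seq_len(n_desc) / n_desc
  floor_g <- stats::runif(1, config$freefall_floor_range[1], config$freefall_floor_range[2])
  # support is lost quickly: magnitude reaches the free-fall floor by 60% of
  # the descent and dwells there until impact
  s_u <- ifelse(u < 0.6, (1 + cos(pi * u / 0.6)) / 2, 0)
  mag_desc <- floor_g + (1 - floor_g) * s_u
  tilt <- 0.35 * sin(pi * u)          # growing lean toward the landing axis
  dirs <- normalize_rows(outer(1 - tilt, c(0, 0, 1)) + outer(tilt, template$land))
  acc_desc <- dirs * mag_desc
  gyro_desc <- matrix(0, n_desc, 3)
  gyro_peak <- stats::runif(1, 100, 300)
  gyro_desc[, template$gyro_axis] <- gyro_peak * sin(pi * u)
  desc <- cbind(acc_desc, gyro_desc)

  # (iii) impact + settling in the landing orientation
  n_imp <- round(0.12 * rate)
  n_settle <- round(0.8 * rate)
  peak <- stats::runif(1, config$impact_peak_range[1], config$impact_peak_range[2])
  t_imp <- (seq_len(n_imp) - 0.5) / rate
  pulse <- exp(-((t_imp - 0.04) / 0.012)^2)
  v <- seq_len(n_imp) / n_imp
  dir_imp <- normalize_rows(outer(1 - v, dirs[n_desc, ]) + outer(v, template$land))
  acc_imp <- dir_imp * (1 + (peak - 1) * pulse)
  gyro_imp <- matrix(0, n_imp, 3)
  gyro_imp[, template$gyro_axis] <- gyro_peak * exp(-6 * t_imp / max(t_imp))
  t_set <- seq_len(n_settle) / rate
  wob <- 0.15 * gain * exp(-3 * t_set) * sin(2 * pi * 4 * t_set)
  acc_set <- outer(1 + wob, template$land)
  settle <- cbind(acc_set, matrix(0, n_settle, 3))

  # (iv) post-fall tail, removed before labeling
  n_tail <- round(1.0 * rate)
  tail_ <- cbind(outer(rep(1, n_tail), template$land), matrix(0, n_tail, 3))

  x <- rbind(pre, desc, cbind(acc_imp, gyro_imp), settle, tail_)
  x <- add_sensor_noise(x, config$noise_sd)
  colnames(x) <- sim_channel_names()
  trial <- recording_trial(x, rate_hz = rate, activity_code = template$code,
                           is_fall_activity = TRUE)
  ann <- stage_annotation(n_pre, n_pre + n_desc,
                          n_pre + n_desc + n_imp + n_settle)
  list(trial = trial, annotation = ann)
}

normalize_rows <- function(m) m / sqrt(rowSums(m^2))

#' Simulate a full annotated cohort
#'
#' Draws per-subject random effects once per subject, then generates
#' `trials_per_subject` trials of every ADL and fall template for each
#' subject. Deterministic under `config$seed`. Optionally writes the cohort
#' to disk in the SisFall text dialect (9-channel files: the low-range
#' second accelerometer is emulated by clipping the wide-range one at
#' +/- 8 g), with the annotation sidecar CSV and a manifest JSON.
#'
#' @param config A [sim_cohort_config()].
#' @param dir Optional output directory; created if needed.
#' @return An object of class `imu_cohort`: list with `trials` (6-channel
#'   [recording_trial()]s), `annotations` (parallel named list), `subjects`
#'   (data frame id/group) and `config`.
#' @export
simulate_cohort <- function(config = sim_cohort_config(), dir = NULL) {
  set.seed(config$seed)
  n_sub <- config$n_young + config$n_elderly
  if (n_sub == 0L) warning("empty cohort: no subjects configured", call. = FALSE)
  subjects <- data.frame(
    subject_id = c(sprintf("SA%02d", seq_len(config$n_young)),
                   sprintf("SE%02d", seq_len(config$n_elderly))),
    subject_group = rep(c("young", "elderly"), c(config$n_young, config$n_elderly)),
    stringsAsFactors = FALSE
  )
  trials <- list(); annotations <- list()
  templates <- c(config$adl_types, config$fall_types)
  is_fall <- c(rep(FALSE, length(config$adl_types)), rep(TRUE, length(config$fall_types)))
  for (i in seq_len(nrow(subjects))) {
    sp <- draw_subject_params()
    for (j in seq_along(templates)) {
      for (r in seq_len(config$trials_per_subject)) {
        sim <- if (is_fall[j]) simulate_fall_trial(templates[[j]], sp, config)
               else simulate_adl_trial(templates[[j]], sp, config)
        tr <- sim$trial
        tr$subject_id <- subjects$subject_id[i]
        tr$subject_group <- subjects$subject_group[i]
        tr$trial_index <- r
        id <- sub("\\.txt$", "", trial_filename(tr))
        trials[[id]] <- tr
        annotations[[id]] <- sim$annotation
      }
    }
  }
  cohort <- structure(list(trials = trials, annotations = annotations,
                           subjects = subjects, config = config),
                      class = "imu_cohort")
  if (!is.null(dir)) write_cohort(cohort, dir)
  cohort
}

#' @export
print.imu_cohort <- function(x, ...) {
  cat(sprintf("<imu_cohort> %d subjects (%d young, %d elderly), %d trials\n",
              nrow(x$subjects), sum(x$subjects$subject_group == "young"),
              sum(x$subjects$subject_group == "elderly"), length(x$trials)))
  invisible(x)
}

#' Write a cohort to disk in the SisFall dialect
#'
#' @param cohort An `imu_cohort`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  schema <- sisfall_sensor_schema()
  for (id in names(cohort$trials)) {
    tr <- cohort$trials[[id]]
    x6 <- tr$samples
    acc2 <- pmin(pmax(x6[, 1:3], -8), 8)   # emulated low-range accelerometer
    tr9 <- tr
    tr9$samples <- cbind(x6, acc2)
    write_trial(tr9, file.path(dir, paste0(id, ".txt")), schema)
  }
  write_annotations(cohort$annotations, file.path(dir, "annotations.csv"))
  manifest <- list(seed = cohort$config$seed,
                   n_young = cohort$config$n_young,
                   n_elderly = cohort$config$n_elderly,
                   trials_per_subject = cohort$config$trials_per_subject,
                   rate_hz = cohort$config$rate_hz,
                   n_trials = length(cohort$trials),
                   templates = vapply(c(cohort$config$adl_types, cohort$config$fall_types),
                                      `[[`, character(1), "name"))
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(dir)
}

#' Load a cohort written by [write_cohort()] (or real SisFall-style files)
#'
#' @param dir Directory with `*.txt` trials and `annotations.csv`.
#' @param channel_spec Channels to keep; default first accelerometer + gyro.
#' @param schema Sensor schema for ADC conversion.
#' @return An `imu_cohort` with 6-channel trials.
#' @export
load_cohort <- function(dir, channel_spec = 1:6, schema = sisfall_sensor_schema()) {
  files <- sort(list.files(dir, pattern = "\\.txt$", full.names = TRUE))
  if (length(files) == 0L) stop(sprintf("no trial files in %s", dir), call. = FALSE)
  ann <- read_annotations(file.path(dir, "annotations.csv"))
  trials <- lapply(files, function(f) select_channels(read_trial(f, schema), channel_spec))
  ids <- sub("\\.txt$", "", basename(files))
  names(trials) <- ids
  missing <- setdiff(ids, names(ann))
  if (length(missing) > 0L) {
    stop(sprintf("annotations missing for: %s", paste(missing, collapse = ", ")), call. = FALSE)
  }
  subjects <- unique(data.frame(
    subject_id = vapply(trials, `[[`, character(1), "subject_id"),
    subject_group = vapply(trials, `[[`, character(1), "subject_group"),
    stringsAsFactors = FALSE))
  rownames(subjects) <- NULL
  structure(list(trials = trials, annotations = ann[ids], subjects = subjects,
                 config = NULL),
            class = "imu_cohort")
}

#' Build a labeled window set directly from a cohort
#'
#' @param cohort An `imu_cohort`.
#' @inheritParams build_dataset
#' @return A `window_set`.
#' @export
cohort_windows <- function(cohort, window_len = 256L, stride = 128L,
                           rule = "final_sample", verbose = FALSE) {
  build_dataset(unname(cohort$trials), unname(cohort$annotations),
                window_len = window_len, stride = stride, rule = rule,
                verbose = verbose)
}
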