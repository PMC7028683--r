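# Independent brute-force reference implementations ("oracles") that the
# package code is checked against. They are written in the most literal way
# possible - explicit loops over instances, direct transcriptions of the
# definitions - and deliberately share no code with the package.

# One-vs-rest confusion counts by looping over every instance.
brute_confusion <- function(y_true, y_pred, cls) {
  tp <- fn <- tn <- fp <- 0L
  for (i in seq_along(y_true)) {
    if (y_true[i] == cls) {
      if (y_pred[i] == cls) tp <- tp + 1L else fn <- fn + 1L
    } else {
      if (y_pred[i] == cls) fp <- fp + 1L else tn <- tn + 1L
    }
  }
  list(tp = tp, fn = fn, tn = tn, fp = fp)
}

# Sensitivity / specificity / accuracy straight from their defining ratios.
brute_metrics <- function(cc) {
  list(sensitivity = cc$tp / (cc$tp + cc$fn),
       specificity = cc$tn / (cc$tn + cc$fp),
       accuracy = (cc$tp + cc$tn) / (cc$tp + cc$fn + cc$tn + cc$fp))
}

# Mean cross-entropy of the true-class probabilities, computed directly.
brute_cross_entropy <- function(probs, labels) {
  s <- 0
  for (i in seq_len(nrow(probs))) s <- s - log(probs[i, labels[i] + 1L])
  s / nrow(probs)
}

# Epoch-selection rule by exhaustive enumeration over all epochs: rank every
# epoch by total evaluation sensitivity (ties toward the earlier epoch), keep
# the top three, and among those return the epoch with the highest
# non-fall + pre-impact sum, again breaking ties toward the earlier epoch.
brute_best_epoch <- function(history) {
  tot <- history$eval_sens_nonfall + history$eval_sens_preimpact + history$eval_sens_fall
  ranked <- history$epoch[order(-tot, history$epoch)]
  top3 <- ranked[seq_len(min(3L, length(ranked)))]
  best <- NA_integer_; best_key <- -Inf
  for (ep in sort(top3)) {
    row <- history[history$epoch == ep, ]
    key <- row$eval_sens_nonfall + row$eval_sens_preimpact
    if (key > best_key) { best <- ep; best_key <- key }
  }
  best
}

# Stage of one 0-based sample index under an annotation (per-sample lookup).
brute_stage_of <- function(i, ann) {
  if (i < ann$pre_impact_start) 0L
  else if (i < ann$pre_impact_end) 1L
  else if (i < ann$fall_end) 2L
  else stop("index beyond fall_end")
}

# Majority-overlap label of a span by counting each sample's stage, ties
# resolved toward the later (more dangerous) stage.
brute_majority_label <- function(span, ann) {
  stages <- vapply(span[1]:(span[2] - 1L), brute_stage_of, integer(1), ann = ann)
  counts <- vapply(0:2, function(k) sum(stages == k), integer(1))
  max(which(counts == max(counts))) - 1L
}

# Threshold fall detector used to check the simulator's separability
# guarantee: a fall shows a sub-threshold dip of the smoothed acceleration
# magnitude (support loss during descent) followed by a > 2 g impact peak.
roll_mean <- function(x, k) {
  cs <- cumsum(c(0, x))
  (cs[(k + 1):length(cs)] - cs[1:(length(cs) - k)]) / k
}

threshold_fall_detector <- function(samples, rate_hz = 200,
                                    smooth_s = 0.1, dip_g = 0.55, peak_g = 2) {
  mag <- sqrt(rowSums(samples[, 1:3]^2))
  sm <- roll_mean(mag, max(2L, round(smooth_s * rate_hz)))
  dips <- which(sm < dip_g)
  if (length(dips) == 0L) return(FALSE)
  any(mag[dips[1]:length(mag)] > peak_g)
}

# A random 6-channel trial for structural tests (not physically meaningful).
random_trial <- function(n = 600L, C = 6L, subject_id = "SA01",
                         activity_code = "D01", trial_index = 1L) {
  recording_trial(matrix(stats::rnorm(n * C), n, C), rate_hz = 200,
                  subject_id = subject_id,
                  subject_group = if (startsWith(subject_id, "SE")) "elderly" else "young",
                  activity_code = activity_code, trial_index = trial_index)
}

# Tiny experiment profile for CLI tests: 4 subjects, 1 trial per template,
# a narrow ConvLSTM and 2 epochs - finishes in seconds but exercises the
# whole simulate -> window -> split -> train -> report pipeline.
tiny_experiment_config <- function(out_dir, seed = 7L) {
  experiment_config(
    sim = sim_cohort_config(n_young = 2L, n_elderly = 2L, trials_per_subject = 1L,
                            seed = seed),
    model = model_config("convlstm", width = 8L),
    train = train_config(n_epochs = 2L, seed = seed),
    folds_seed = 1L, folds = 1L, n_folds = 2L,
    out_dir = out_dir
  )
}
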