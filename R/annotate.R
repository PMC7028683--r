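#' Stage annotation for one trial
#'
#' Delimits the three stages of a recording with 0-based, half-open sample
#' intervals: `[0, pre_impact_start)` is non-fall, `[pre_impact_start,
#' pre_impact_end)` is pre-impact fall (descent, before body-ground impact)
#' and `[pre_impact_end, fall_end)` is fall (impact and settling). Samples at
#' or beyond `fall_end` are post-fall and removed before labeling. A pure-ADL
#' trial sets all three indices to the trial length T (no pre-impact or fall
#' interval).
#'
#' @param pre_impact_start,pre_impact_end,fall_end 0-based sample indices
#'   with `0 <= pre_impact_start <= pre_impact_end <= fall_end`.
#' @return An object of class `stage_annotation`.
#' @export
stage_annotation <- function(pre_impact_start, pre_impact_end, fall_end) {
  v <- c(pre_impact_start, pre_impact_end, fall_end)
  if (anyNA(v) || any(v < 0) || is.unsorted(v)) {
    stop("stage_annotation: need 0 <= pre_impact_start <= pre_impact_end <= fall_end",
         call. = FALSE)
  }
  structure(list(pre_impact_start = as.integer(pre_impact_start),
                 pre_impact_end = as.integer(pre_impact_end),
                 fall_end = as.integer(fall_end)),
            class = "stage_annotation")
}

#' @export
print.stage_annotation <- function(x, ...) {
  cat(sprintf("<stage_annotation> pre-impact [%d, %d), fall [%d, %d)\n",
              x$pre_impact_start, x$pre_impact_end, x$pre_impact_end, x$fall_end))
  invisible(x)
}

#' Class labels
#'
#' Integer codes used throughout: 0 = non-fall, 1 = pre-impact fall, 2 = fall.
#' @return Named integer vector.
#' @export
fall_stage_labels <- function() {
  c(nonfall = 0L, preimpact = 1L, fall = 2L)
}

#' Per-sample stage table
#'
#' Stage code of every sample of a (truncated) trial of length `n`, under an
#' annotation. Used as the brute-force reference the window-labeling rule is
#' checked against.
#'
#' @param ann A [stage_annotation()].
#' @param n Trial length; defaults to `ann$fall_end`.
#' @return Integer vector of length `n` with values in 0..2.
#' @export
stage_table <- function(ann, n = ann$fall_end) {
  idx <- seq_len(n) - 1L  # 0-based
  out <- integer(n)
  out[idx >= ann$pre_impact_start & idx < ann$pre_impact_end] <- 1L
  out[idx >= ann$pre_impact_end & idx < ann$fall_end] <- 2L
  out
}

#' Remove post-fall data from a trial
#'
#' Everything at or beyond `fall_end` is the state after the fall incident
#' and is removed before labeling. ADL trials (`fall_end == T`) come back
#' unchanged. A `fall_end` of 0 yields a degenerate empty trial, marked with
#' attribute `degenerate = TRUE` so downstream segmentation can skip it.
#'
#' @param trial A [recording_trial()].
#' @param ann A [stage_annotation()] valid for the trial length.
#' @return The truncated trial.
#' @export
truncate_post_fall <- function(trial, ann) {
  T_ <- nrow(trial$samples)
  if (ann$fall_end > T_) {
    stop(sprintf("annotation error: fall_end (%d) exceeds trial length (%d)",
                 ann$fall_end, T_), call. = FALSE)
  }
  if (ann$fall_end == T_) return(trial)
  trial$samples <- trial$samples[seq_len(ann$fall_end), , drop = FALSE]
  if (ann$fall_end == 0L) attr(trial, "degenerate") <- TRUE
  trial
}

#' Enumerate sliding-window spans over a trial
#'
#' Spans are 0-based half-open intervals `[s, s + window_len)` with starts
#' `s = 0, stride, 2*stride, ...`; the count is
#' `floor((T - window_len) / stride) + 1`. Trials shorter than one window
#' produce an empty set with a warning (the trial is skipped, not padded).
#'
#' @param trial A [recording_trial()] (already truncated).
#' @param window_len Window length in samples; default 256 (the model input).
#' @param stride Step between starts, `1 <= stride <= window_len`; default
#'   128 (50% overlap).
#' @return Integer matrix with columns `start`, `end` (0-based half-open),
#'   zero rows if the trial is too short.
#' @export
segment_windows <- function(trial, window_len = 256L, stride = 128L) {
  window_len <- as.integer(window_len); stride <- as.integer(stride)
  if (window_len < 1L) stop("segment_windows: window_len must be >= 1", call. = FALSE)
  if (stride < 1L || stride > window_len) {
    stop("segment_windows: need 1 <= stride <= window_len", call. = FALSE)
  }
  T_ <- nrow(trial$samples)
  if (isTRUE(attr(trial, "degenerate")) || T_ < window_len) {
    warning(sprintf("trial %s_%s_R%02d shorter than one window (%d < %d); skipped",
                    trial$activity_code, trial$subject_id, trial$trial_index,
                    T_, window_len), call. = FALSE)
    return(matrix(integer(0), ncol = 2, dimnames = list(NULL, c("start", "end"))))
  }
  starts <- seq.int(0L, T_ - window_len, by = stride)
  cbind(start = starts, end = starts + window_len)
}

#' Label one window span
#'
#' The default, causal rule labels a window by the stage of its final sample:
#' at inference time the window end is "now", which matches real-time
#' pre-impact prediction. The alternative `"majority"` rule takes the stage
#' covering the largest share of the window (ties go to the later stage, the
#' more safety-critical call).
#'
#' @param span Length-2 vector or one row of [segment_windows()] output,
#'   0-based half-open `[start, end)`.
#' @param ann A [stage_annotation()].
#' @param rule `"final_sample"` (default) or `"majority"`.
#' @return Integer class label in 0..2 (see [fall_stage_labels()]).
#' @export
assign_window_label <- function(span, ann, rule = c("final_sample", "majority")) {
  if (is.character(rule)) {
    if (!rule[1] %in% c("final_sample", "majority")) {
      stop(sprintf("unknown labeling rule '%s'", rule[1]), call. = FALSE)
    }
    rule <- rule[1]
  } else stop("unknown labeling rule", call. = FALSE)
  start <- span[[1]]; end <- span[[2]]
  if (start < 0 || end > ann$fall_end || end <= start) {
    stop("assign_window_label: span outside the truncated trial", call. = FALSE)
  }
  stage_of <- function(i) {  # i is 0-based
    if (i < ann$pre_impact_start) 0L
    else if (i < ann$pre_impact_end) 1L
    else 2L
  }
  if (rule == "final_sample") {
    stage_of(end - 1L)
  } else {
    counts <- c(
      max(0L, min(end, ann$pre_impact_start) - start),
      max(0L, min(end, ann$pre_impact_end) - max(start, ann$pre_impact_start)),
      max(0L, end - max(start, ann$pre_impact_end))
    )
    # ties resolved toward the later (more dangerous) stage
    max(which(counts == max(counts))) - 1L
  }
}

#' Build a labeled window set from annotated trials
#'
#' Composes truncation, segmentation and labeling over a cohort: each trial
#' is cut at `fall_end`, sliced into overlapping windows, and every window is
#' assigned one of the three stage labels. Per-window provenance (subject,
#' activity, trial, start index) is retained so subject-wise splits can be
#' enforced at window granularity.
#'
#' @param trials List of [recording_trial()] (6 channels each).
#' @param annotations List of [stage_annotation()], parallel to `trials`.
#' @param window_len,stride See [segment_windows()].
#' @param rule See [assign_window_label()].
#' @param verbose Log class counts after windowing.
#' @return An object of class `window_set`: list with `windows` (array
#'   N x L x C), `labels` (integer N, 0..2), `provenance` (data frame),
#'   and the segmentation settings.
#' @export
build_dataset <- function(trials, annotations, window_len = 256L, stride = 128L,
                          rule = "final_sample", verbose = FALSE) {
  stopifnot(length(trials) == length(annotations))
  if (length(trials) == 0L) stop("build_dataset: no trials", call. = FALSE)
  per <- vector("list", length(trials))
  for (i in seq_along(trials)) {
    tr <- truncate_post_fall(trials[[i]], annotations[[i]])
    spans <- suppressWarnings(segment_windows(tr, window_len, stride))
    if (nrow(spans) == 0L) next
    labs <- vapply(seq_len(nrow(spans)),
                   function(j) assign_window_label(spans[j, ], annotations[[i]], rule),
                   integer(1))
    per[[i]] <- list(trial = tr, spans = spans, labels = labs, idx = i)
  }
  per <- per[!vapply(per, is.null, logical(1))]
  if (length(per) == 0L) stop("build_dataset: no trial long enough for one window", call. = FALSE)
  n <- sum(vapply(per, function(p) nrow(p$spans), integer(1)))
  C <- ncol(per[[1]]$trial$samples)
  windows <- array(0, dim = c(n, window_len, C))
  labels <- integer(n)
  k <- 0L
  for (p in per) {
    tr <- p$trial
    for (j in seq_len(nrow(p$spans))) {
      k <- k + 1L
      s <- p$spans[j, "start"]
      windows[k, , ] <- tr$samples[(s + 1L):(s + window_len), , drop = FALSE]
      labels[k] <- p$labels[j]
    }
  }
  prov <- do.call(rbind, lapply(per, function(p) {
    data.frame(subject_id = p$trial$subject_id,
               subject_group = p$trial$subject_group,
               activity_code = p$trial$activity_code,
               trial_index = p$trial$trial_index,
               start = p$spans[, "start"],
               stringsAsFactors = FALSE)
  }))
  rownames(prov) <- NULL
  ws <- structure(
    list(windows = windows, labels = labels, provenance = prov,
         window_len = as.integer(window_len), stride = as.integer(stride),
         rule = rule, label_map = fall_stage_labels()),
    class = "window_set"
  )
  if (verbose) {
    cts <- window_class_counts(ws)
    message(sprintf("window set: %d windows (non-fall %d, pre-impact %d, fall %d)",
                    n, cts[1], cts[2], cts[3]))
  }
  ws
}

#' @export
print.window_set <- function(x, ...) {
  cts <- window_class_counts(x)
  cat(sprintf("<window_set> %d windows of %d x %d (stride %d, rule %s)\n",
              length(x$labels), x$window_len, dim(x$windows)[3], x$stride, x$rule))
  cat(sprintf("  classes: non-fall %d | pre-impact %d | fall %d\n", cts[1], cts[2], cts[3]))
  invisible(x)
}

#' Class counts of a window set
#' @param ws A `window_set`.
#' @return Integer vector of length 3 (non-fall, pre-impact, fall).
#' @export
window_class_counts <- function(ws) {
  vapply(0:2, function(k) sum(ws$labels == k), integer(1))
}

#' Subset a window set by row index or subject
#'
#' @param ws A `window_set`.
#' @param idx Integer row indices, or use `subjects` to select by provenance.
#' @param subjects Character vector of subject ids (used if `idx` missing).
#' @return A `window_set` restricted to the selected windows.
#' @export
subset_windows <- function(ws, idx = NULL, subjects = NULL) {
  if (is.null(idx)) {
    if (is.null(subjects)) stop("subset_windows: give `idx` or `subjects`", call. = FALSE)
    idx <- which(ws$provenance$subject_id %in% subjects)
  }
  ws$windows <- ws$windows[idx, , , drop = FALSE]
  ws$labels <- ws$labels[idx]
  ws$provenance <- ws$provenance[idx, , drop = FALSE]
  rownames(ws$provenance) <- NULL
  ws
}

#' Save / load a window set
#'
#' The arrays, labels and provenance go into one container file (RDS), and a
#' JSON manifest next to it records window length, stride, labeling rule and
#' class counts for provenance.
#'
#' @param ws A `window_set`.
#' @param path Container file path (`.rds`); the manifest is written to
#'   `paste0(path, ".json")`.
#' @return `path`, invisibly.
#' @export
save_window_set <- function(ws, path) {
  saveRDS(ws, path)
  cts <- window_class_counts(ws)
  manifest <- list(window_len = ws$window_len, stride = ws$stride, rule = ws$rule,
                   n_windows = length(ws$labels),
                   class_counts = list(nonfall = cts[1], preimpact = cts[2], fall = cts[3]))
  jsonlite::write_json(manifest, paste0(path, ".json"), auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}

#' @rdname save_window_set
#' @export
load_window_set <- function(path) readRDS(path)
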