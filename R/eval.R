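#' One-vs-rest confusion counts for one class
#'
#' For class `k`: TP are instances of `k` classified as `k`; FN are instances
#' of `k` classified otherwise; TN are instances of the other two classes not
#' classified as `k`; FP are instances of the other classes wrongly
#' classified as `k`. The four counts always partition the instances.
#'
#' @param y_true,y_pred Integer label vectors in 0..2, equal length >= 1.
#' @param cls Class id in 0..2.
#' @return Object of class `confusion_counts`: list `tp`, `fn`, `tn`, `fp`.
#' @export
confusion_counts <- function(y_true, y_pred, cls) {
  if (length(y_true) != length(y_pred) || length(y_true) < 1L) {
    stop("confusion_counts: label vectors must be non-empty and equal length", call. = FALSE)
  }
  if (any(!c(y_true, y_pred) %in% 0:2)) {
    stop("confusion_counts: labels must be in {0, 1, 2}", call. = FALSE)
  }
  pos_t <- y_true == cls; pos_p <- y_pred == cls
  structure(list(tp = sum(pos_t & pos_p), fn = sum(pos_t & !pos_p),
                 tn = sum(!pos_t & !pos_p), fp = sum(!pos_t & pos_p)),
            class = "confusion_counts")
}

#' Per-class sensitivity, specificity and accuracy
#'
#' Sensitivity = TP / (TP + FN); Specificity = TN / (TN + FP);
#' Accuracy = (TP + TN) / (TP + FP + TN + FN), all from one class's
#' one-vs-rest counts.
#'
#' @param cc A [confusion_counts()].
#' @param cls Optional class name for error messages.
#' @return Object of class `class_metrics`: list `sensitivity`,
#'   `specificity`, `accuracy`, each in `[0, 1]`.
#' @export
class_metrics <- function(cc, cls = NULL) {
  who <- if (is.null(cls)) "" else sprintf(" for class '%s'", cls)
  if (cc$tp + cc$fn == 0L) {
    stop(sprintf("undefined sensitivity%s: no positive instances", who), call. = FALSE)
  }
  if (cc$tn + cc$fp == 0L) {
    stop(sprintf("undefined specificity%s: no negative instances", who), call. = FALSE)
  }
  structure(list(
    sensitivity = cc$tp / (cc$tp + cc$fn),
    specificity = cc$tn / (cc$tn + cc$fp),
    accuracy = (cc$tp + cc$tn) / (cc$tp + cc$fp + cc$tn + cc$fn)
  ), class = "class_metrics")
}

#' Subject-wise five-fold splits
#'
#' Subjects, not windows, are partitioned: elderly subjects are randomly
#' divided into `n_folds` groups as evenly as possible (15 elderly -> five
#' groups of 3), young subjects likewise (23 young -> groups of 5, 5, 5, 4,
#' 4), and each elderly group is randomly paired with one young group to
#' form a fold's test set; the training set is the complement. No subject
#' ever appears in two test folds, so the ~80/20 train/test splits are free
#' of subject leakage.
#'
#' @param elderly_ids,young_ids Character vectors of subject ids.
#' @param n_folds Number of folds (5).
#' @param seed Optional seed; when NULL the current RNG state is used.
#' @return List of `n_folds` fold splits: `fold`, `test_subjects`,
#'   `train_subjects`.
#' @export
make_subjectwise_folds <- function(elderly_ids, young_ids, n_folds = 5L, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n_folds <- as.integer(n_folds)
  if (length(elderly_ids) < n_folds) {
    stop(sprintf("split error: %d elderly subjects cannot fill %d folds",
                 length(elderly_ids), n_folds), call. = FALSE)
  }
  if (anyDuplicated(c(elderly_ids, young_ids))) {
    stop("split error: duplicated subject ids", call. = FALSE)
  }
  even_groups <- function(ids, k) {
    n <- length(ids)
    sizes <- rep(n %/% k, k)
    extra <- n %% k
    if (extra > 0) sizes[seq_len(extra)] <- sizes[seq_len(extra)] + 1L
    shuffled <- sample(ids)
    split(shuffled, rep(seq_len(k), times = sizes))
  }
  eg <- even_groups(elderly_ids, n_folds)
  yg <- if (length(young_ids) > 0) even_groups(young_ids, n_folds)
        else rep(list(character(0)), n_folds)
  pairing <- sample.int(n_folds)   # random elderly-young group combination
  all_ids <- c(elderly_ids, young_ids)
  lapply(seq_len(n_folds), function(f) {
    test <- c(eg[[f]], yg[[pairing[f]]])
    list(fold = f, test_subjects = sort(test),
         train_subjects = sort(setdiff(all_ids, test)))
  })
}

#' Subject-wise cross-validation of one model family
#'
#' Builds the labeled window set once, then for every fold trains a fresh
#' model on the training subjects' windows, applies the top-3
#' summation-sensitivity epoch-selection rule, and computes per-class
#' sensitivity/specificity/accuracy at the selected epoch from the fold's
#' evaluation confusion counts. Windows of one subject never appear in both
#' sets (asserted at window granularity). The report's summary is the mean
#' of the fold metrics (macro over folds); a class absent from a fold's test
#' set yields NA metrics for that fold, never 0.
#'
#' @param cohort An `imu_cohort`.
#' @param model_cfg A [model_config()].
#' @param train_cfg A [train_config()].
#' @param window_len,stride,rule Windowing settings (see [build_dataset()]).
#' @param folds_seed Seed for the subject split.
#' @param folds Which folds to run (default all 5).
#' @param n_folds Number of folds.
#' @param pooled Also report metrics from confusion counts summed over folds
#'   (micro averaging). The macro mean stays the headline number; pooling
#'   weights folds by their window counts instead of equally.
#' @param verbose Per-epoch logging.
#' @return Object of class `cv_report`: `folds` (per-fold metrics and
#'   selected epoch), `mean` (macro-averaged metrics matrix), `pooled`
#'   (micro-averaged matrix, when requested), `settings`.
#' @export
cross_validate <- function(cohort, model_cfg = model_config("convlstm"),
                           train_cfg = train_config(), window_len = 256L,
                           stride = 128L, rule = "final_sample",
                           folds_seed = 1L, folds = NULL, n_folds = 5L,
                           pooled = FALSE, verbose = FALSE) {
  ws <- cohort_windows(cohort, window_len, stride, rule)
  elderly <- cohort$subjects$subject_id[cohort$subjects$subject_group == "elderly"]
  young <- cohort$subjects$subject_id[cohort$subjects$subject_group == "young"]
  splits <- make_subjectwise_folds(elderly, young, n_folds = n_folds, seed = folds_seed)
  run <- folds %||% seq_len(n_folds)
  fold_results <- lapply(splits[run], function(sp) {
    tr_ws <- subset_windows(ws, subjects = sp$train_subjects)
    te_ws <- subset_windows(ws, subjects = sp$test_subjects)
    leak <- intersect(unique(tr_ws$provenance$subject_id),
                      unique(te_ws$provenance$subject_id))
    stopifnot(length(leak) == 0L)
    model <- build_model(model_cfg, seed = train_cfg$seed + sp$fold)
    fit <- train_model(model, tr_ws, te_ws, train_cfg, verbose = verbose)
    h <- fit$history[fit$history$epoch == fit$best_epoch, ]
    metrics <- lapply(0:2, function(k) {
      cc <- structure(list(tp = h[[sprintf("eval_tp_%d", k)]],
                           fn = h[[sprintf("eval_fn_%d", k)]],
                           tn = h[[sprintf("eval_tn_%d", k)]],
                           fp = h[[sprintf("eval_fp_%d", k)]]),
                      class = "confusion_counts")
      tryCatch(class_metrics(cc, cls = names(fall_stage_labels())[k + 1]),
               error = function(e) {
                 structure(list(sensitivity = NA_real_, specificity = NA_real_,
                                accuracy = NA_real_), class = "class_metrics")
               })
    })
    names(metrics) <- names(fall_stage_labels())
    list(fold = sp$fold, test_subjects = sp$test_subjects,
         best_epoch = fit$best_epoch, metrics = metrics,
         history = fit$history, model = fit$model)
  })
  metric_array <- vapply(fold_results, function(fr) {
    vapply(fr$metrics, function(m) c(m$sensitivity, m$specificity, m$accuracy),
           numeric(3))
  }, matrix(0, 3, 3))   # [metric, class, fold]
  dimnames(metric_array) <- list(c("sensitivity", "specificity", "accuracy"),
                                 names(fall_stage_labels()),
                                 paste0("fold", vapply(fold_results, `[[`, integer(1), "fold")))
  mean_metrics <- apply(metric_array, c(1, 2), mean, na.rm = TRUE)
  pooled_metrics <- NULL
  if (isTRUE(pooled)) {
    pooled_metrics <- vapply(0:2, function(k) {
      cc <- structure(as.list(colSums(do.call(rbind, lapply(fold_results, function(fr) {
        h <- fr$history[fr$history$epoch == fr$best_epoch, ]
        c(tp = h[[sprintf("eval_tp_%d", k)]], fn = h[[sprintf("eval_fn_%d", k)]],
          tn = h[[sprintf("eval_tn_%d", k)]], fp = h[[sprintf("eval_fp_%d", k)]])
      })))), class = "confusion_counts")
      m <- tryCatch(class_metrics(cc), error = function(e) {
        list(sensitivity = NA_real_, specificity = NA_real_, accuracy = NA_real_)
      })
      c(m$sensitivity, m$specificity, m$accuracy)
    }, numeric(3))
    dimnames(pooled_metrics) <- list(c("sensitivity", "specificity", "accuracy"),
                                     names(fall_stage_labels()))
  }
  structure(list(folds = fold_results, fold_metrics = metric_array,
                 mean = mean_metrics, pooled = pooled_metrics,
                 settings = list(model = model_cfg, train = train_cfg,
                                 window_len = window_len, stride = stride,
                                 rule = rule, folds_seed = folds_seed,
                                 n_folds = n_folds, folds_run = run)),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report> %s, %d fold(s)\n", x$settings$model$family, length(x$folds)))
  cat("mean over folds (%):\n")
  print(round(100 * x$mean, 2))
  invisible(x)
}

#' Per-instance inference latency
#'
#' Times single-window forward passes (batch size 1 - the streaming
#' deployment scenario), excluding warm-up passes, and reports the mean and
#' standard deviation of per-instance wall-clock time in milliseconds.
#' Absolute values are hardware-dependent; only within-machine comparisons
#' between model families are meaningful.
#'
#' @param model A `fall_model`.
#' @param windows A `window_set` with at least `min_instances` windows
#'   (instances are recycled if fewer are requested).
#' @param n_instances How many timed passes.
#' @param n_warmup Untimed warm-up passes.
#' @param min_instances Required window count.
#' @return List `mean_ms`, `sd_ms`, `n`.
#' @export
measure_latency <- function(model, windows, n_instances = 200L, n_warmup = 10L,
                            min_instances = 100L) {
  N <- length(windows$labels)
  if (N == 0L) stop("measurement error: empty window set", call. = FALSE)
  if (N < min_instances) {
    stop(sprintf("measurement error: need >= %d instances, have %d", min_instances, N),
         call. = FALSE)
  }
  pick <- rep_len(seq_len(N), n_warmup + n_instances)
  for (i in seq_len(n_warmup)) {
    invisible(predict_proba(model, windows$windows[pick[i], , ], batch_size = 1L))
  }
  times <- numeric(n_instances)
  for (i in seq_len(n_instances)) {
    x <- windows$windows[pick[n_warmup + i], , ]
    t0 <- Sys.time()
    invisible(predict_proba(model, x, batch_size = 1L))
    times[i] <- as.numeric(difftime(Sys.time(), t0, units = "secs")) * 1000
  }
  list(mean_ms = mean(times), sd_ms = stats::sd(times), n = n_instances)
}
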