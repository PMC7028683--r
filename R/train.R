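#' Training configuration
#'
#' Defaults follow the study protocol: batch size 64, 200 epochs, learning
#' rate 0.0005, focal loss. The optimizer is Adam with no schedule or weight
#' decay. Focal-loss parameters: `gamma = 2` (the canonical focusing
#' strength) and `alpha = "auto"`, inverse class frequency on the training
#' windows normalized to mean 1 - the dataset is dominated by non-fall
#' windows and the loss, not resampling, carries the imbalance handling.
#'
#' @param batch_size Mini-batch size.
#' @param n_epochs Number of epochs.
#' @param learning_rate Adam step size.
#' @param focal_gamma Focusing parameter, >= 0. At 0 (with uniform alpha) the
#'   loss is exactly mean cross-entropy.
#' @param focal_alpha `"auto"`, a single positive weight, or one positive
#'   weight per class.
#' @param seed Seed controlling initialization order, shuffling and dropout.
#' @return An object of class `train_config`.
#' @export
train_config <- function(batch_size = 64L, n_epochs = 200L, learning_rate = 0.0005,
                         focal_gamma = 2, focal_alpha = "auto", seed = 1L) {
  if (focal_gamma < 0) stop("train_config: focal_gamma must be >= 0", call. = FALSE)
  if (is.numeric(focal_alpha) && any(focal_alpha <= 0)) {
    stop("train_config: alpha weights must be positive", call. = FALSE)
  }
  structure(list(batch_size = as.integer(batch_size), n_epochs = as.integer(n_epochs),
                 learning_rate = learning_rate, loss = "focal",
                 focal_gamma = focal_gamma, focal_alpha = focal_alpha,
                 optimizer = "adam", seed = as.integer(seed)),
            class = "train_config")
}

#' Focal loss
#'
#' `FL(p_t) = -alpha_t * (1 - p_t)^gamma * log(p_t)`, averaged over the
#' batch, where `p_t` is the predicted probability of the true class. The
#' `(1 - p_t)^gamma` factor down-weights easy, well-classified examples so
#' rare classes (pre-impact, fall) are not drowned out by the dominant
#' non-fall windows. With `gamma = 0` and `alpha = 1` it reduces exactly to
#' mean cross-entropy. Probabilities are clamped at `1e-7` so the loss is
#' never NaN.
#'
#' @param probs Matrix `[B, K]` of rows on the probability simplex.
#' @param labels Integer vector of true classes in `0..K-1`.
#' @param gamma Focusing parameter >= 0.
#' @param alpha Scalar or per-class positive weights.
#' @return Non-negative scalar loss.
#' @export
focal_loss <- function(probs, labels, gamma = 2, alpha = 1) {
  B <- nrow(probs); K <- ncol(probs)
  if (any(labels < 0L | labels >= K)) stop("focal_loss: label out of range", call. = FALSE)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  pt <- probs[cbind(seq_len(B), labels + 1L)]
  pt <- pmax(pt, 1e-7)
  at <- alpha[labels + 1L]
  mean(-at * (1 - pt)^gamma * log(pt))
}

# Gradient of the batch-mean focal loss wrt the logits, via the softmax
# Jacobian: dL/dz_j = p_j * (g_j - sum_k g_k p_k) with g = dL/dp.
focal_loss_grad <- function(logits, labels, gamma = 2, alpha = 1) {
  probs <- softmax_rows(logits)
  B <- nrow(probs); K <- ncol(probs)
  if (length(alpha) == 1L) alpha <- rep(alpha, K)
  pt <- pmax(probs[cbind(seq_len(B), labels + 1L)], 1e-7)
  at <- alpha[labels + 1L]
  # dL/dp_t = -alpha * [ (1-p)^g / p - g * (1-p)^(g-1) * log(p) ]
  om <- 1 - pt
  dpt <- -at * (om^gamma / pt - if (gamma > 0) gamma * om^(gamma - 1) * log(pt) else 0)
  G <- matrix(0, B, K)
  G[cbind(seq_len(B), labels + 1L)] <- dpt
  inner <- rowSums(G * probs)
  dZ <- probs * (G - inner)
  list(loss = mean(-at * om^gamma * log(pt)), dlogits = dZ / B, probs = probs)
}

resolve_alpha <- function(focal_alpha, labels, n_classes = 3L) {
  if (identical(focal_alpha, "auto")) {
    freq <- vapply(seq_len(n_classes) - 1L, function(k) sum(labels == k), numeric(1))
    if (any(freq == 0)) stop("training error: a class is absent from the training set",
                             call. = FALSE)
    a <- 1 / freq
    a / mean(a)
  } else if (length(focal_alpha) == 1L) {
    rep(focal_alpha, n_classes)
  } else focal_alpha
}

# per-class sensitivity (recall) from hard labels; NA when a class is absent
sensitivities <- function(y_true, y_pred, n_classes = 3L) {
  vapply(seq_len(n_classes) - 1L, function(k) {
    n <- sum(y_true == k)
    if (n == 0L) return(NA_real_)
    sum(y_true == k & y_pred == k) / n
  }, numeric(1))
}

#' Train a model
#'
#' Mini-batch Adam on the focal loss, fully deterministic given
#' `config$seed` (data order, dropout masks). Every epoch records per-class
#' sensitivities on the training set (from the training passes themselves,
#' i.e. with dropout and batch statistics active, the usual learning-curve
#' convention) and on the evaluation set (a full inference pass), plus the
#' evaluation-set one-vs-rest confusion counts; the per-epoch history is
#' what the top-3 epoch-selection rule (see
#' [select_best_epoch()]) operates on. Parameter snapshots are kept for the
#' epochs currently in the top 3 by total evaluation sensitivity, so the
#' selected epoch's model is returned without storing every epoch.
#'
#' Note the evaluation set here plays the role of the test fold: per-epoch
#' test-set sensitivity drives epoch selection, reproducing the original
#' protocol literally. That choice is optimistic (the test fold influences
#' which epoch is reported) and is documented as such.
#'
#' @param model A `fall_model` from [build_model()].
#' @param train_windows,eval_windows `window_set`s; the training set must
#'   contain all three classes.
#' @param config A [train_config()].
#' @param verbose Print one line per epoch.
#' @return List of class `train_result`: `history` (data frame, one row per
#'   epoch), `model` (parameters of the selected epoch), `best_epoch`,
#'   `final_model` (end-of-training parameters), `alpha` (resolved class
#'   weights).
#' @export
train_model <- function(model, train_windows, eval_windows, config = train_config(),
                        verbose = FALSE) {
  if (length(train_windows$labels) == 0L || length(eval_windows$labels) == 0L) {
    stop("train_model: empty window set", call. = FALSE)
  }
  if (config$n_epochs == 0L) {
    return(structure(list(history = empty_history(), model = model,
                          best_epoch = NA_integer_, final_model = model,
                          alpha = NULL),
                     class = "train_result"))
  }
  alpha <- resolve_alpha(config$focal_alpha, train_windows$labels, model$config$n_classes)
  set.seed(config$seed)
  state <- adam_init(model)
  N <- length(train_windows$labels)
  bs <- config$batch_size
  hist <- vector("list", config$n_epochs)
  snaps <- list()   # epoch -> parameter snapshot, pruned to current top 3
  step <- 0L
  for (ep in seq_len(config$n_epochs)) {
    ord <- sample.int(N)
    ep_loss <- 0; n_batches <- 0L
    tr_pred <- integer(N)   # training-pass predictions, for the training curve
    for (s in seq.int(1L, N, by = bs)) {
      idx <- ord[s:min(s + bs - 1L, N)]
      xb <- train_windows$windows[idx, , , drop = FALSE]
      yb <- train_windows$labels[idx]
      fw <- model_forward(model, xb, training = TRUE)
      model <- fw$model
      lg <- focal_loss_grad(fw$logits, yb, config$focal_gamma, alpha)
      if (!is.finite(lg$loss)) {
        stop(sprintf("training aborted: non-finite loss at epoch %d (lr %g, batch %d)",
                     ep, config$learning_rate, n_batches + 1L), call. = FALSE)
      }
      tr_pred[idx] <- max.col(lg$probs) - 1L
      grads <- model_backward(model, fw$caches, lg$dlogits, length(idx))
      step <- step + 1L
      upd <- adam_step(model, grads, state, config$learning_rate, step)
      model <- upd$model; state <- upd$state
      ep_loss <- ep_loss + lg$loss; n_batches <- n_batches + 1L
    }
    ev_pred <- predict_labels(model, eval_windows$windows)
    tr_sens <- sensitivities(train_windows$labels, tr_pred)
    ev_sens <- sensitivities(eval_windows$labels, ev_pred)
    cc <- lapply(0:2, function(k) confusion_counts(eval_windows$labels, ev_pred, k))
    hist[[ep]] <- data.frame(
      epoch = ep, train_loss = ep_loss / n_batches,
      train_sens_nonfall = tr_sens[1], train_sens_preimpact = tr_sens[2],
      train_sens_fall = tr_sens[3],
      eval_sens_nonfall = ev_sens[1], eval_sens_preimpact = ev_sens[2],
      eval_sens_fall = ev_sens[3],
      eval_tp_0 = cc[[1]]$tp, eval_fn_0 = cc[[1]]$fn, eval_tn_0 = cc[[1]]$tn, eval_fp_0 = cc[[1]]$fp,
      eval_tp_1 = cc[[2]]$tp, eval_fn_1 = cc[[2]]$fn, eval_tn_1 = cc[[2]]$tn, eval_fp_1 = cc[[2]]$fp,
      eval_tp_2 = cc[[3]]$tp, eval_fn_2 = cc[[3]]$fn, eval_tn_2 = cc[[3]]$tn, eval_fp_2 = cc[[3]]$fp
    )
    if (verbose) {
      message(sprintf("epoch %3d loss %.4f | eval sens %.3f %.3f %.3f", ep,
                      ep_loss / n_batches, ev_sens[1], ev_sens[2], ev_sens[3]))
    }
    # keep snapshots only for the current top-3 epochs by total eval sensitivity
    h <- do.call(rbind, hist[seq_len(ep)])
    top3 <- top3_epochs(h)
    if (ep %in% top3) snaps[[as.character(ep)]] <- model_snapshot(model)
    snaps <- snaps[names(snaps) %in% as.character(top3)]
  }
  history <- do.call(rbind, hist)
  best <- select_best_epoch(history)
  best_model <- model_restore(model, snaps[[as.character(best)]])
  structure(list(history = history, model = best_model, best_epoch = best,
                 final_model = model, alpha = alpha),
            class = "train_result")
}

empty_history <- function() {
  df <- data.frame(epoch = integer(0), train_loss = numeric(0),
                   train_sens_nonfall = numeric(0), train_sens_preimpact = numeric(0),
                   train_sens_fall = numeric(0),
                   eval_sens_nonfall = numeric(0), eval_sens_preimpact = numeric(0),
                   eval_sens_fall = numeric(0))
  for (k in 0:2) for (m in c("tp", "fn", "tn", "fp")) df[[sprintf("eval_%s_%d", m, k)]] <- integer(0)
  df
}

total_eval_sens <- function(history) {
  rowSums(history[, c("eval_sens_nonfall", "eval_sens_preimpact", "eval_sens_fall")],
          na.rm = FALSE)
}

top3_epochs <- function(history) {
  tot <- total_eval_sens(history)
  ord <- order(-tot, history$epoch)   # ties: earlier epoch first
  history$epoch[ord[seq_len(min(3L, nrow(history)))]]
}

#' Select the reporting epoch from a training history
#'
#' Among the three epochs with the highest summation sensitivity over all
#' three classes on the evaluation set, returns the one whose summation
#' sensitivity over non-fall and pre-impact fall is highest - balancing the
#' three classes without losing focus on the pre-impact stage. Ties break
#' toward the earliest epoch.
#'
#' @param history Data frame with columns `epoch`, `eval_sens_nonfall`,
#'   `eval_sens_preimpact`, `eval_sens_fall` (as produced by
#'   [train_model()]).
#' @return The selected epoch number.
#' @export
select_best_epoch <- function(history) {
  if (is.null(history) || nrow(history) == 0L) {
    stop("select_best_epoch: empty training history", call. = FALSE)
  }
  cand <- history[history$epoch %in% top3_epochs(history), , drop = FALSE]
  key <- cand$eval_sens_nonfall + cand$eval_sens_preimpact
  ord <- order(-key, cand$epoch)
  cand$epoch[ord[1]]
}

#' Write a training history as a learning-curve CSV
#'
#' @param history The `history` data frame of a [train_model()] result.
#' @param path Output CSV (one row per epoch).
#' @return `path`, invisibly.
#' @export
write_history <- function(history, path) {
  utils::write.csv(history, path, row.names = FALSE)
  invisible(path)
}
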