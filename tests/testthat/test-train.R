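# Training: focal loss and its gradient, class-weight resolution, the
# training loop's determinism and bookkeeping, and the epoch-selection rule.

random_simplex_rows <- function(B, K = 3L) {
  z <- matrix(rexp(B * K), B, K)
  z / rowSums(z)
}

# a small separable window set: class k lives at mean level k
toy_window_set <- function(n_per_class = 12L, L = 20L, C = 6L, seed = 1L) {
  set.seed(seed)
  n <- 3L * n_per_class
  labels <- rep(0:2, each = n_per_class)
  windows <- array(rnorm(n * L * C, sd = 0.3), c(n, L, C)) +
    array(rep(labels, L * C), c(n, L, C))
  prov <- data.frame(subject_id = sprintf("SA%02d", rep(1:3, each = n_per_class)),
                     subject_group = "young", activity_code = "D01",
                     trial_index = 1L, start = 0L, stringsAsFactors = FALSE)
  structure(list(windows = windows, labels = labels, provenance = prov,
                 window_len = L, stride = L, rule = "final_sample",
                 label_map = fall_stage_labels()),
            class = "window_set")
}

toy_model <- function(seed = 2L, L = 20L) {
  build_model(model_config("lstm", width = 6L, n_lstm_layers = 1L,
                           dropout = 0, input_len = L), seed = seed)
}

test_that("training defaults match the study protocol", {
  cfg <- train_config()
  expect_equal(cfg$batch_size, 64L)
  expect_equal(cfg$n_epochs, 200L)
  expect_equal(cfg$learning_rate, 0.0005)
  expect_equal(cfg$loss, "focal")
  expect_equal(cfg$optimizer, "adam")
  expect_equal(cfg$focal_gamma, 2)
  expect_identical(cfg$focal_alpha, "auto")
  expect_error(train_config(focal_gamma = -1), "gamma")
  expect_error(train_config(focal_alpha = c(1, 0, 1)), "positive")
})

test_that("focal loss is zero at certainty and never NaN at zero probability", {
  probs <- diag(3)[c(1, 2, 3, 1), ]
  expect_equal(focal_loss(probs, c(0, 1, 2, 0), gamma = 2, alpha = 1), 0)
  probs0 <- matrix(c(0, 1, 0), 1, 3)   # true class has probability exactly 0
  expect_true(is.finite(focal_loss(probs0, 0L, gamma = 2, alpha = 1)))
  expect_error(focal_loss(probs, c(0, 1, 3, 0)), "out of range")
})

test_that("with gamma 0 and unit alpha the focal loss is mean cross-entropy", {
  set.seed(71)
  for (rep in 1:25) {
    B <- sample(2:40, 1)
    probs <- random_simplex_rows(B)
    labels <- sample(0:2, B, replace = TRUE)
    expect_equal(focal_loss(probs, labels, gamma = 0, alpha = 1),
                 brute_cross_entropy(probs, labels), tolerance = 1e-10)
  }
})

test_that("raising gamma strictly lowers the loss on a well-classified batch", {
  set.seed(72)
  B <- 16L
  probs <- 0.05 * random_simplex_rows(B)
  labels <- sample(0:2, B, replace = TRUE)
  probs[cbind(seq_len(B), labels + 1L)] <- 0   # rebuild rows with p_t > 0.9
  probs <- probs / rowSums(probs) * 0.08
  probs[cbind(seq_len(B), labels + 1L)] <- 0.92
  losses <- vapply(c(0, 0.5, 1, 2, 4), function(g) focal_loss(probs, labels, g, 1),
                   numeric(1))
  expect_true(all(diff(losses) < 0))
})

test_that("the loss is invariant to sample order within a batch", {
  set.seed(73)
  probs <- random_simplex_rows(20)
  labels <- sample(0:2, 20, replace = TRUE)
  perm <- sample(20)
  expect_equal(focal_loss(probs, labels, 2, c(1.2, 0.7, 1.1)),
               focal_loss(probs[perm, ], labels[perm], 2, c(1.2, 0.7, 1.1)))
})

test_that("the focal gradient matches finite differences of the loss in the logits", {
  set.seed(74)
  for (gamma in c(0, 1, 2)) {
    B <- 6L
    logits <- matrix(rnorm(B * 3), B, 3)
    labels <- sample(0:2, B, replace = TRUE)
    alpha <- c(1.5, 0.8, 0.7)
    lg <- fallnet:::focal_loss_grad(logits, labels, gamma, alpha)
    h <- 1e-6
    for (i in seq_len(B)) for (j in 1:3) {
      lp <- logits; lp[i, j] <- lp[i, j] + h
      lm <- logits; lm[i, j] <- lm[i, j] - h
      num <- (focal_loss(fallnet:::softmax_rows(lp), labels, gamma, alpha) -
              focal_loss(fallnet:::softmax_rows(lm), labels, gamma, alpha)) / (2 * h)
      expect_equal(lg$dlogits[i, j], num, tolerance = 1e-5)
    }
    expect_equal(lg$loss, focal_loss(fallnet:::softmax_rows(logits), labels, gamma, alpha))
  }
})

test_that("automatic alpha is inverse class frequency normalized to mean one", {
  labels <- c(rep(0L, 60), rep(1L, 10), rep(2L, 30))
  a <- fallnet:::resolve_alpha("auto", labels)
  raw <- 1 / c(60, 10, 30)
  expect_equal(a, raw / mean(raw))
  expect_equal(mean(a), 1)
  expect_gt(a[2], a[1])   # the rare class carries the largest weight
  expect_error(fallnet:::resolve_alpha("auto", rep(0L, 5)), "absent")
  expect_equal(fallnet:::resolve_alpha(0.5, labels), rep(0.5, 3))
})

test_that("training is deterministic and records one epoch row with confusion counts", {
  ws <- toy_window_set()
  cfg <- train_config(batch_size = 12L, n_epochs = 3L, learning_rate = 0.01, seed = 5L)
  fit1 <- train_model(toy_model(), ws, ws, cfg)
  fit2 <- train_model(toy_model(), ws, ws, cfg)
  expect_identical(fit1$history, fit2$history)
  expect_equal(nrow(fit1$history), 3L)
  expect_true(all(c("epoch", "train_loss", "eval_sens_preimpact",
                    "eval_tp_1", "eval_fp_2") %in% names(fit1$history)))
  # confusion counts partition the evaluation set in every epoch
  n <- length(ws$labels)
  for (k in 0:2) {
    tot <- fit1$history[[sprintf("eval_tp_%d", k)]] +
      fit1$history[[sprintf("eval_fn_%d", k)]] +
      fit1$history[[sprintf("eval_tn_%d", k)]] +
      fit1$history[[sprintf("eval_fp_%d", k)]]
    expect_true(all(tot == n))
  }
  expect_true(fit1$best_epoch %in% 1:3)
  # the returned model reproduces the selected epoch's evaluation predictions
  h <- fit1$history[fit1$history$epoch == fit1$best_epoch, ]
  pred <- predict_labels(fit1$model, ws$windows)
  expect_equal(sum(ws$labels == 0 & pred == 0), h$eval_tp_0)
  expect_equal(sum(ws$labels == 1 & pred == 1), h$eval_tp_1)
})

test_that("zero-epoch training returns an empty history and an untouched model", {
  ws <- toy_window_set()
  m <- toy_model()
  fit <- train_model(m, ws, ws, train_config(n_epochs = 0L))
  expect_equal(nrow(fit$history), 0L)
  expect_true(is.na(fit$best_epoch))
  expect_identical(fallnet:::model_snapshot(fit$model), fallnet:::model_snapshot(m))
})

test_that("training refuses empty window sets and training sets missing a class", {
  ws <- toy_window_set()
  empty <- subset_windows(ws, idx = integer(0))
  expect_error(train_model(toy_model(), empty, ws, train_config(n_epochs = 1L)),
               "empty window set")
  two_class <- subset_windows(ws, idx = which(ws$labels != 1L))
  expect_error(train_model(toy_model(), two_class, ws,
                           train_config(n_epochs = 1L)), "absent")
})

test_that("a few epochs on a separable toy set reach high training sensitivity", {
  ws <- toy_window_set()
  cfg <- train_config(batch_size = 12L, n_epochs = 8L, learning_rate = 0.02, seed = 3L)
  fit <- train_model(toy_model(), ws, ws, cfg)
  last <- fit$history[nrow(fit$history), ]
  expect_gt(last$eval_sens_nonfall, 0.9)
  expect_gt(last$eval_sens_preimpact, 0.9)
  expect_gt(last$eval_sens_fall, 0.9)
  expect_lt(last$train_loss, fit$history$train_loss[1])
})

test_that("the worked epoch-selection example picks the top-3 epoch with best alert sum", {
  # three-class sums 2.7, 2.8, 2.9, 2.85 and non-fall+pre-impact sums
  # 1.8, 1.9, 1.85, 1.95: epochs 2..4 are the top 3 by total, and epoch 4
  # has the highest non-fall + pre-impact sum among them
  alert_sums <- c(1.8, 1.9, 1.85, 1.95)
  total_sums <- c(2.7, 2.8, 2.9, 2.85)
  history <- data.frame(
    epoch = 1:4,
    eval_sens_nonfall = alert_sums / 2,
    eval_sens_preimpact = alert_sums / 2,
    eval_sens_fall = total_sums - alert_sums
  )
  expect_equal(select_best_epoch(history), 4L)
  expect_equal(brute_best_epoch(history), 4L)
})

test_that("a single epoch selects itself and full ties resolve to the earliest epoch", {
  one <- data.frame(epoch = 1L, eval_sens_nonfall = 0.5,
                    eval_sens_preimpact = 0.5, eval_sens_fall = 0.5)
  expect_equal(select_best_epoch(one), 1L)
  flat <- data.frame(epoch = 1:6, eval_sens_nonfall = 0.8,
                     eval_sens_preimpact = 0.8, eval_sens_fall = 0.8)
  expect_equal(select_best_epoch(flat), 1L)
  expect_error(select_best_epoch(flat[0, ]), "empty")
})

test_that("the selected epoch always lies in the top 3 by total sensitivity", {
  set.seed(75)
  for (rep in 1:50) {
    n <- sample(1:30, 1)
    history <- data.frame(epoch = seq_len(n),
                          eval_sens_nonfall = round(runif(n), 2),
                          eval_sens_preimpact = round(runif(n), 2),
                          eval_sens_fall = round(runif(n), 2))
    sel <- select_best_epoch(history)
    tot <- history$eval_sens_nonfall + history$eval_sens_preimpact + history$eval_sens_fall
    top3 <- history$epoch[order(-tot, history$epoch)][seq_len(min(3, n))]
    expect_true(sel %in% top3)
    expect_equal(sel, brute_best_epoch(history))
  }
})

test_that("learning-curve CSVs round-trip the history", {
  ws <- toy_window_set()
  fit <- train_model(toy_model(), ws, ws,
                     train_config(batch_size = 12L, n_epochs = 2L,
                                  learning_rate = 0.01, seed = 5L))
  path <- file.path(withr::local_tempdir(), "curve.csv")
  write_history(fit$history, path)
  back <- utils::read.csv(path)
  expect_equal(back$epoch, fit$history$epoch)
  expect_equal(back$train_loss, fit$history$train_loss, tolerance = 1e-12)
  expect_equal(back$eval_tp_1, fit$history$eval_tp_1)
})
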