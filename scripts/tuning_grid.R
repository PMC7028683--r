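#!/usr/bin/env Rscript
# Optional experiment: replay the 24-cell hybrid-model hyperparameter grid.
#
# Usage:
#   Rscript scripts/tuning_grid.R [--epochs <int>] [--seed <int>] [--out <csv>]
#
# Trains one ConvLSTM per cell of the grid
#   width {32, 64, 128} x conv blocks {2, 4} x LSTM layers {2, 4}
#   x dropout {0.5, 0.8}
# on the synthetic cohort (train on 7 subjects, evaluate on a fixed 3-subject
# holdout) and ranks the cells by summation evaluation sensitivity at each
# cell's selected epoch. The package default ConvLSTM configuration (width
# 64, 4 conv blocks, 2 LSTM layers, dropout 0.5) is the winner of this grid
# in the original full-scale protocol; on the synthetic cohort the ranking is
# illustrative, not evidence. At the default 20 epochs the sweep takes a few
# hours on one CPU core — it is NOT part of the test suite.

suppressPackageStartupMessages(library(fallnet))

args <- commandArgs(trailingOnly = TRUE)
opt <- list(epochs = 20L, seed = 42L, out = "tuning_grid.csv")
i <- 1L
while (i <= length(args)) {
  if (args[i] == "--epochs") { opt$epochs <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--seed") { opt$seed <- as.integer(args[i + 1L]); i <- i + 2L }
  else if (args[i] == "--out") { opt$out <- args[i + 1L]; i <- i + 2L }
  else stop(sprintf("unknown argument '%s'", args[i]))
}

cohort <- simulate_cohort(sim_cohort_config())
ws <- cohort_windows(cohort, window_len = 256L, stride = 64L)
held_out <- c("SA01", "SA02", "SE01")
train_ws <- subset_windows(ws, subjects = setdiff(cohort$subjects$subject_id, held_out))
eval_ws <- subset_windows(ws, subjects = held_out)

grid <- expand.grid(width = c(32L, 64L, 128L),
                    n_conv_blocks = c(2L, 4L),
                    n_lstm_layers = c(2L, 4L),
                    dropout = c(0.5, 0.8))
cat(sprintf("%d grid cells, %d epochs each\n", nrow(grid), opt$epochs))

rows <- lapply(seq_len(nrow(grid)), function(g) {
  cfg <- model_config("convlstm",
                      width = grid$width[g],
                      n_conv_blocks = grid$n_conv_blocks[g],
                      n_lstm_layers = grid$n_lstm_layers[g],
                      dropout = grid$dropout[g])
  fit <- train_model(build_model(cfg, seed = opt$seed), train_ws, eval_ws,
                     train_config(n_epochs = opt$epochs, seed = opt$seed))
  h <- fit$history[fit$history$epoch == fit$best_epoch, ]
  summation <- h$eval_sens_nonfall + h$eval_sens_preimpact + h$eval_sens_fall
  cat(sprintf("cell %2d/%d: width %3d, conv %d, lstm %d, dropout %.1f -> summation %.4f (epoch %d)\n",
              g, nrow(grid), grid$width[g], grid$n_conv_blocks[g],
              grid$n_lstm_layers[g], grid$dropout[g], summation, fit$best_epoch))
  data.frame(grid[g, ], best_epoch = fit$best_epoch,
             sens_nonfall = h$eval_sens_nonfall,
             sens_preimpact = h$eval_sens_preimpact,
             sens_fall = h$eval_sens_fall,
             summation_sensitivity = summation)
})

tab <- do.call(rbind, rows)
tab <- tab[order(-tab$summation_sensitivity), ]
rownames(tab) <- NULL
utils::write.csv(tab, opt$out, row.names = FALSE)
cat(sprintf("\nranked grid written to %s; best cell:\n", opt$out))
print(tab[1, ])
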