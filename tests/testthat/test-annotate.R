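# Three-stage labeling: annotations, post-fall truncation, sliding-window
# segmentation, window labeling rules, and window-set assembly.

test_that("stage annotations enforce ordered non-negative indices", {
  ann <- stage_annotation(600, 700, 880)
  expect_s3_class(ann, "stage_annotation")
  expect_error(stage_annotation(-1, 5, 10), "0 <=")
  expect_error(stage_annotation(10, 5, 20), "0 <=")
  expect_error(stage_annotation(5, 30, 20), "0 <=")
  expect_error(stage_annotation(NA, 5, 10), "0 <=")
})

test_that("the per-sample stage table matches a direct per-index lookup", {
  set.seed(21)
  for (rep in 1:20) {
    b <- sort(sample(0:50, 3, replace = TRUE))
    ann <- stage_annotation(b[1], b[2], b[3])
    n <- b[3]
    if (n == 0) next
    tab <- stage_table(ann, n)
    ref <- vapply(seq_len(n) - 1L, brute_stage_of, integer(1), ann = ann)
    expect_equal(tab, ref)
  }
})

test_that("post-fall truncation cuts at fall_end and leaves ADL trials unchanged", {
  tr <- random_trial(2000)
  cut <- truncate_post_fall(tr, stage_annotation(1200, 1350, 1500))
  expect_equal(nrow(cut$samples), 1500L)
  expect_equal(cut$samples, tr$samples[1:1500, ])
  adl <- truncate_post_fall(tr, stage_annotation(2000, 2000, 2000))
  expect_identical(adl$samples, tr$samples)
  expect_error(truncate_post_fall(tr, stage_annotation(100, 200, 2001)),
               "exceeds trial length")
})

test_that("a zero-length truncation is flagged degenerate and skipped downstream", {
  tr <- random_trial(400)
  cut <- truncate_post_fall(tr, stage_annotation(0, 0, 0))
  expect_true(isTRUE(attr(cut, "degenerate")))
  expect_warning(spans <- segment_windows(cut, 256, 128), "skipped")
  expect_equal(nrow(spans), 0L)
})

test_that("window counts follow the closed form floor((T - L) / stride) + 1", {
  tr <- random_trial(1000)
  expect_equal(nrow(segment_windows(tr, 256, 128)), 6L)
  tr256 <- random_trial(256)
  expect_equal(nrow(segment_windows(tr256, 256, 1)), 1L)
  expect_equal(nrow(segment_windows(tr256, 256, 256)), 1L)
  set.seed(31)
  for (rep in 1:25) {
    T_ <- sample(50:800, 1); L <- sample(10:50, 1); s <- sample(seq_len(L), 1)
    spans <- segment_windows(random_trial(T_), L, s)
    # brute-force enumeration of admissible starts
    starts <- 0L
    while (utils::tail(starts, 1) + s + L <= T_) starts <- c(starts, utils::tail(starts, 1) + s)
    expect_equal(nrow(spans), (T_ - L) %/% s + 1L)
    expect_equal(unname(spans[, "start"]), starts)
    expect_true(all(spans[, "end"] - spans[, "start"] == L))
    expect_true(all(spans[, "end"] <= T_))
  }
})

test_that("segmentation rejects invalid window and stride settings, skips short trials", {
  tr <- random_trial(100)
  expect_error(segment_windows(tr, 0, 1), "window_len")
  expect_error(segment_windows(tr, 10, 0), "stride")
  expect_error(segment_windows(tr, 10, 11), "stride")
  expect_warning(spans <- segment_windows(tr, 256, 128), "shorter than one window")
  expect_equal(nrow(spans), 0L)
})

test_that("the final-sample rule labels every span by the stage of its last sample", {
  set.seed(41)
  for (rep in 1:20) {
    b <- sort(sample(0:300, 3, replace = TRUE))
    ann <- stage_annotation(b[1], b[2], b[3])
    if (b[3] < 16) next
    tr <- random_trial(b[3])
    spans <- segment_windows(tr, 16, 4)
    for (j in seq_len(nrow(spans))) {
      expect_identical(assign_window_label(spans[j, ], ann),
                       brute_stage_of(spans[j, "end"] - 1L, ann))
    }
  }
})

test_that("a span entirely before the pre-impact onset is non-fall under both rules", {
  ann <- stage_annotation(500, 600, 800)
  expect_equal(assign_window_label(c(0, 256), ann, "final_sample"), 0L)
  expect_equal(assign_window_label(c(0, 256), ann, "majority"), 0L)
  # ending inside the pre-impact interval -> alert under the causal rule
  expect_equal(assign_window_label(c(300, 556), ann, "final_sample"), 1L)
})

test_that("the majority rule matches brute-force stage counting with later-stage ties", {
  set.seed(51)
  for (rep in 1:30) {
    b <- sort(sample(0:120, 3, replace = TRUE))
    ann <- stage_annotation(b[1], b[2], b[3])
    if (b[3] < 10) next
    spans <- segment_windows(random_trial(b[3]), 10, 3)
    for (j in seq_len(nrow(spans))) {
      expect_identical(assign_window_label(spans[j, ], ann, "majority"),
                       brute_majority_label(spans[j, ], ann))
    }
  }
  # an exact two-way tie goes to the later, more dangerous stage
  ann <- stage_annotation(5, 10, 20)
  expect_equal(assign_window_label(c(0, 10), ann, "majority"), 1L)
  expect_equal(assign_window_label(c(5, 15), ann, "majority"), 2L)
})

test_that("unknown labeling rules and out-of-bounds spans are rejected", {
  ann <- stage_annotation(5, 10, 20)
  expect_error(assign_window_label(c(0, 10), ann, "centroid"), "unknown labeling rule")
  expect_error(assign_window_label(c(-1, 9), ann), "outside")
  expect_error(assign_window_label(c(0, 21), ann), "outside")
  expect_error(assign_window_label(c(5, 5), ann), "outside")
})

test_that("an ADL-only dataset is all non-fall; a well-covered fall trial shows all stages", {
  adl <- random_trial(600, activity_code = "D01")
  ws <- build_dataset(list(adl), list(stage_annotation(600, 600, 600)),
                      window_len = 64, stride = 32)
  expect_true(all(ws$labels == 0L))
  fall <- random_trial(600, activity_code = "F01")
  ann <- stage_annotation(300, 400, 580)
  ws2 <- build_dataset(list(fall), list(ann), window_len = 64, stride = 16)
  expect_setequal(unique(ws2$labels), 0:2)
})

test_that("dataset size equals the sum of per-trial span counts and copies exact samples", {
  trials <- list(random_trial(500, subject_id = "SA01"),
                 random_trial(700, subject_id = "SA02", activity_code = "F01"),
                 random_trial(300, subject_id = "SE01"))
  anns <- list(stage_annotation(500, 500, 500),
               stage_annotation(400, 500, 650),
               stage_annotation(300, 300, 300))
  L <- 64L; s <- 32L
  ws <- build_dataset(trials, anns, L, s)
  expected_n <- sum(vapply(seq_along(trials), function(i) {
    (anns[[i]]$fall_end - L) %/% s + 1L
  }, integer(1)))
  expect_equal(length(ws$labels), expected_n)
  expect_equal(dim(ws$windows), c(expected_n, L, 6L))
  expect_equal(nrow(ws$provenance), expected_n)
  # spot-check the raw copy for a window of the second (truncated) trial
  i <- which(ws$provenance$subject_id == "SA02")[3]
  st <- ws$provenance$start[i]
  expect_equal(ws$windows[i, , ], trials[[2]]$samples[(st + 1):(st + L), ],
               ignore_attr = TRUE)
  # no window references samples at or beyond fall_end
  for (k in seq_along(trials)) {
    rows <- ws$provenance$subject_id == trials[[k]]$subject_id
    expect_true(all(ws$provenance$start[rows] + L <= anns[[k]]$fall_end))
  }
})

test_that("changing the stride changes window counts but never a shared window's label", {
  tr <- random_trial(900, activity_code = "F02")
  ann <- stage_annotation(450, 560, 880)
  ws_fine <- build_dataset(list(tr), list(ann), 64, 8)
  ws_coarse <- build_dataset(list(tr), list(ann), 64, 32)
  expect_gt(length(ws_fine$labels), length(ws_coarse$labels))
  common <- match(ws_coarse$provenance$start, ws_fine$provenance$start)
  expect_false(anyNA(common))
  expect_equal(ws_fine$labels[common], ws_coarse$labels)
})

test_that("window subsets by subject partition the set without altering provenance", {
  trials <- list(random_trial(500, subject_id = "SA01"),
                 random_trial(500, subject_id = "SE01"))
  anns <- list(stage_annotation(500, 500, 500), stage_annotation(500, 500, 500))
  ws <- build_dataset(trials, anns, 64, 64)
  a <- subset_windows(ws, subjects = "SA01")
  b <- subset_windows(ws, subjects = "SE01")
  expect_equal(length(a$labels) + length(b$labels), length(ws$labels))
  expect_true(all(a$provenance$subject_id == "SA01"))
  expect_true(all(b$provenance$subject_id == "SE01"))
  expect_error(subset_windows(ws), "idx.*subjects")
  idx <- c(2L, 5L)
  expect_equal(subset_windows(ws, idx = idx)$windows[2, , ], ws$windows[5, , ])
})

test_that("window sets persist with a manifest recording settings and class counts", {
  tr <- random_trial(600, activity_code = "F01")
  ws <- build_dataset(list(tr), list(stage_annotation(300, 400, 580)), 64, 16)
  path <- file.path(withr::local_tempdir(), "ws.rds")
  save_window_set(ws, path)
  back <- load_window_set(path)
  expect_equal(back$windows, ws$windows)
  expect_equal(back$labels, ws$labels)
  man <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  expect_equal(man$window_len, 64L)
  expect_equal(man$stride, 16L)
  expect_equal(man$n_windows, length(ws$labels))
  expect_equal(unlist(man$class_counts), window_class_counts(ws), ignore_attr = TRUE)
})
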