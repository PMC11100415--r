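test_that("rms_envelope matches the frame-by-frame loop oracle", {
  set.seed(41)
  for (p in list(c(4, 2), c(5, 3), c(7, 1))) {
    x <- matrix(rnorm(60), 20, 3)
    expect_equal(rms_envelope(x, p[1], p[2]), rms_oracle(x, p[1], p[2]),
                 tolerance = 1e-12)
  }
  # larger randomized case at the documented 1e-10 agreement
  x <- matrix(rnorm(3e4), 1e4, 3)
  expect_lt(max(abs(rms_envelope(x, 200, 7) - rms_oracle(x, 200, 7))), 1e-10)
})

test_that("rms_envelope closed forms and frame arithmetic", {
  x <- matrix(-3, 500, 2)
  expect_true(all(abs(rms_envelope(x, 100, 10) - 3) < 1e-12))
  # 100 ms window, 0.5 ms hop at 2 kHz over the full protocol length
  expect_equal(nrow(rms_envelope(matrix(0, 576000, 1), 200, 1)), 575801)
  expect_equal(nrow(rms_envelope(matrix(0, 1000, 1), 200, 100)), 9)
  expect_error(rms_envelope(matrix(0, 100, 1), 200, 1), "insufficient")
})

test_that("mu-law companding: fixed points, value, monotone odd expansion", {
  for (mu in c(1, 50, 255)) {
    expect_identical(mu_law_normalize(0, mu), 0)
    expect_equal(mu_law_normalize(1, mu), 1, tolerance = 1e-15)
  }
  expect_equal(mu_law_normalize(0.5, 255), log1p(127.5) / log1p(255),
               tolerance = 1e-15)
  x <- sort(runif(100, -1, 1))
  y <- mu_law_normalize(x, 255)
  expect_true(all(diff(y) > 0))                       # strictly monotone
  expect_equal(mu_law_normalize(-x, 255), -y)         # odd
  xs <- runif(100, 1e-6, 1 - 1e-6)
  expect_true(all(mu_law_normalize(xs, 255) > xs))    # expands small values
  expect_error(mu_law_normalize(0.5, 0), "positive")
  expect_error(mu_law_normalize(1.5, 255), "\\[-1, 1\\]")
})

test_that("scale_to_unit fits on train data and clips at apply time", {
  set.seed(7)
  f <- matrix(abs(rnorm(40)), 10, 4)
  r <- scale_to_unit(f)
  expect_equal(apply(r$features, 2, max), rep(1, 4))
  held <- f * 2
  ra <- scale_to_unit(held, r$per_channel_max)
  expect_true(all(ra$features <= 1))
  manual <- pmin(sweep(held, 2, r$per_channel_max, "/"), 1)
  expect_equal(ra$features, manual)
  expect_error(scale_to_unit(cbind(f, 0)), "degenerate")
})

test_that("windows respect segment bounds and take the last-frame target", {
  cfg <- tiny_synth()
  rec <- generate_recording(cfg, 1)
  seq <- feature_sequence(rec, tiny_pre())
  # single synthetic segment of exactly L frames -> one window
  one <- fitnet:::subset_sequence(seq, 1:20, rep(1L, 20))
  w1 <- make_windows(one, L = 20L, stride = 1L)
  expect_length(w1$starts, 1)
  expect_equal(w1$y[1, ], seq$angles[20, ])
  # enumeration oracle: 1000-frame segment, L=200, stride=100 -> 9 windows
  long <- fitnet:::subset_sequence(seq, 1:1000, rep(1L, 1000))
  expect_length(make_windows(long, 200L, 100L)$starts, 9)
  # two 300-frame segments, L=200, stride=1: 2 x 101 windows, none crossing
  two <- fitnet:::subset_sequence(seq, 1:600, rep(1:2, each = 300))
  w2 <- make_windows(two, 200L, 1L)
  expect_length(w2$starts, 202)
  expect_true(all((w2$starts <= 101) | (w2$starts >= 301)))
  # short segment skipped with a warning, not an error
  short <- fitnet:::subset_sequence(seq, 1:10, rep(1L, 10))
  expect_warning(w3 <- make_windows(short, 20L, 1L), "skipped")
  expect_length(w3$starts, 0)
})

test_that("7:3 temporal split works per phase segment with leakage guards", {
  cfg <- tiny_synth(n_movements = 2L, n_reps = 2L)
  rec <- generate_recording(cfg, 1)
  pre <- tiny_pre()
  seq <- feature_sequence(rec, pre)
  sp <- split_train_test(seq, 0.7, pre$L)
  guard <- fitnet:::guard_frames(seq)
  runs <- fitnet:::phase_runs(seq)
  for (s in unique(runs)) {
    frames <- seq$frame_end[runs == s]
    n <- length(frames)
    head_guard <- if (s == 1L) 0L else guard
    tr <- sp$train$frame_end[sp$train$frame_end %in% frames]
    te <- sp$test$frame_end[sp$test$frame_end %in% frames]
    expect_length(tr, floor(0.7 * n) - head_guard)
    expect_length(te, n - floor(0.7 * n) - guard)
    # temporal: every train frame of a segment precedes every test frame
    expect_lt(max(tr), min(te))
  }
  # no raw-sample overlap between train and test windows
  wtr <- make_windows(sp$train, pre$L, 3L)
  wte <- make_windows(sp$test, pre$L, 2L)
  expect_no_raw_overlap(wtr, wte, seq$rms_window, seq$rms_step)
  expect_error(split_train_test(seq, 1.2), "ratio")
  w <- testthat::capture_warnings(split_train_test(seq, 0.99, pre$L))
  expect_gt(length(w), 0)
  expect_true(all(grepl("too short", w)))
})

test_that("repetition split holds out whole trials with their rest", {
  cfg <- tiny_synth(n_movements = 2L, n_reps = 3L)
  rec <- generate_recording(cfg, 1)
  pre <- tiny_pre()
  seq <- feature_sequence(rec, pre)
  sp <- split_by_repetition(seq, 0.7, pre$L)
  # round(0.7 * 3) = 2 training repetitions, 1 held out
  expect_setequal(unique(sp$train$repetition[sp$train$movement > 0]), 1:2)
  expect_setequal(unique(sp$test$repetition[sp$test$movement > 0]), 3L)
  # every phase is present on both sides
  expect_true(all(c(0, 1, 2) %in% sp$train$movement))
  expect_true(all(c(0, 1, 2) %in% sp$test$movement))
  # trailing rest follows its trial's side
  expect_setequal(
    unique(sp$test$stream),
    unique(seq$stream[seq$repetition == 3L & seq$movement > 0]))
  # no raw-sample overlap between train and test windows
  wtr <- make_windows(sp$train, pre$L, 3L)
  wte <- make_windows(sp$test, pre$L, 2L)
  expect_no_raw_overlap(wtr, wte, seq$rms_window, seq$rms_step)
  expect_error(split_by_repetition(seq, 1.2), "ratio")
})

test_that("temporal folds partition each stream with disjoint test sets", {
  cfg <- tiny_synth(n_movements = 2L, n_reps = 2L)
  rec <- generate_recording(cfg, 1)
  pre <- tiny_pre()
  seq <- feature_sequence(rec, pre)
  k <- 3L
  folds <- make_folds(seq, k, pre$L)
  expect_length(folds, k)
  test_frames <- lapply(folds, function(f) f$test$frame_end)
  # pairwise disjoint
  for (a in 1:(k - 1)) for (b in (a + 1):k)
    expect_length(intersect(test_frames[[a]], test_frames[[b]]), 0)
  # union covers every frame not removed as a leakage guard
  covered <- sort(unlist(test_frames))
  guard <- fitnet:::guard_frames(seq)
  runs <- fitnet:::phase_runs(seq)
  expect_gte(length(covered), length(seq$frame_end) - 2 * k * guard *
               length(unique(runs)))
  expect_true(all(covered %in% seq$frame_end))
  # fold 1 tests the earliest piece of every phase segment
  run1 <- seq$frame_end[runs == 1L]
  expect_lt(max(intersect(folds[[1]]$test$frame_end, run1)),
            min(intersect(folds[[2]]$test$frame_end, run1)))
  # no raw-sample leakage fold by fold
  for (f in folds) {
    wtr <- make_windows(f$train, pre$L, 4L)
    wte <- make_windows(f$test, pre$L, 3L)
    expect_no_raw_overlap(wtr, wte, seq$rms_window, seq$rms_step)
  }
  expect_error(make_folds(seq, 1L), "k must be")
})

test_that("target scaler round-trips and standardizes training targets", {
  set.seed(9)
  y <- matrix(rnorm(300, mean = 45, sd = 12), 100, 3)
  sc <- fit_target_scaler(y)
  z <- apply_target_scaler(sc, y)
  expect_equal(colMeans(z), rep(0, 3), tolerance = 1e-12)
  expect_equal(apply(z, 2, stats::sd), rep(1, 3), tolerance = 1e-12)
  expect_lt(max(abs(invert_target_scaler(sc, z) - y)), 1e-9)
  # constant column: floored scale, no blow-up
  yc <- cbind(y, 30)
  scc <- fit_target_scaler(yc)
  expect_true(all(is.finite(apply_target_scaler(scc, yc))))
  expect_equal(invert_target_scaler(scc, apply_target_scaler(scc, yc)), yc,
               tolerance = 1e-9)
})

test_that("unit scaling then mu-law keeps features in [0, 1]", {
  set.seed(13)
  f <- matrix(abs(rnorm(200)), 50, 4)
  r <- scale_to_unit(f)
  g <- mu_law_normalize(r$features, 255)
  expect_true(all(g >= 0 & g <= 1))
})
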