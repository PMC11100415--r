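#' Preprocessing configuration
#'
#' Defaults follow the standard recipe for 2 kHz sEMG: RMS envelope over a
#' 100 ms window sliding by 0.5 ms, mu-law companding with mu = 255 after
#' per-channel unit scaling, model windows of L = 200 feature frames, a
#' leakage-safe 7:3 split by repetition, and 5 temporal folds.
#' `train_stride` thins training windows (stride between window starts, in
#' frames); `eval_stride` does the same for evaluation windows.
#'
#' @param rms_window_ms,rms_step_ms RMS envelope window and hop, ms.
#' @param mu mu-law companding parameter.
#' @param L model window length, frames.
#' @param train_stride,eval_stride window strides, frames.
#' @param split_ratio training fraction for the 7:3-style split.
#' @param split_by `"repetition"` assigns whole repetitions to train/test
#'   (the standard protocol for repeated-trial sEMG data, and the default);
#'   `"temporal"` splits each phase segment in time via
#'   [split_train_test()].
#' @param k_folds fold count for [make_folds()].
#' @return an object of class `preprocess_config`.
#' @export
preprocess_config <- function(rms_window_ms = 100, rms_step_ms = 0.5,
                              mu = 255, L = 200L, train_stride = 10L,
                              eval_stride = 1L, split_ratio = 0.7,
                              split_by = c("repetition", "temporal"),
                              k_folds = 5L) {
  split_by <- match.arg(split_by)
  structure(list(rms_window_ms = rms_window_ms, rms_step_ms = rms_step_ms,
                 mu = mu, L = as.integer(L),
                 train_stride = as.integer(train_stride),
                 eval_stride = as.integer(eval_stride),
                 split_ratio = split_ratio, split_by = split_by,
                 k_folds = as.integer(k_folds)),
            class = "preprocess_config")
}

#' Sliding-window RMS envelope
#'
#' Frame k of channel c is `sqrt(mean(x[t, c]^2))` over the `window` samples
#' ending at sample `window + (k-1) * step`; the output has
#' `floor((T - window) / step) + 1` frames.
#'
#' @param emg `T x C` numeric matrix.
#' @param window window size, samples (N in the RMS formula).
#' @param step hop between frames, samples.
#' @return `n_frames x C` matrix of RMS values.
#' @export
rms_envelope <- function(emg, window, step = 1L) {
  emg <- as.matrix(emg)
  Tn <- nrow(emg)
  if (window < 1 || step < 1) stopf("window and step must be >= 1")
  if (Tn < window)
    stopf("insufficient data: %d samples < window of %d", Tn, window)
  ends <- seq(window, Tn, by = step)
  out <- matrix(0, length(ends), ncol(emg))
  for (c in seq_len(ncol(emg))) {
    cs <- cumsum(c(0, emg[, c]^2))
    out[, c] <- sqrt((cs[ends + 1] - cs[ends - window + 1]) / window)
  }
  out
}

#' Mu-law companding
#'
#' `F(x) = sign(x) * log(1 + mu * |x|) / log(1 + mu)`, a strictly monotone,
#' odd map of `[-1, 1]` onto itself that expands small amplitudes; `F(0) = 0`
#' and `F(1) = 1` for any `mu > 0`.
#'
#' @param x numeric array with values in `[-1, 1]`.
#' @param mu positive companding parameter.
#' @return array of the same shape.
#' @export
mu_law_normalize <- function(x, mu = 255) {
  if (mu <= 0) stopf("mu must be positive")
  if (any(abs(x) > 1 + 1e-12, na.rm = TRUE))
    stopf("mu-law input must lie in [-1, 1]; scale features first")
  sign(x) * log1p(mu * abs(x)) / log1p(mu)
}

#' Per-channel unit scaling
#'
#' Divides each channel by its training-set maximum. When `per_channel_max`
#' is `NULL` the maxima are computed from `features` (the fit step);
#' otherwise the given maxima are applied and the result is clipped to
#' `[0, 1]` (the apply step, for held-out data).
#'
#' @param features nonnegative `n x C` matrix (RMS envelopes).
#' @param per_channel_max optional length-C vector of training maxima.
#' @return list with `features` (scaled) and `per_channel_max`.
#' @export
scale_to_unit <- function(features, per_channel_max = NULL) {
  features <- as.matrix(features)
  if (is.null(per_channel_max)) {
    per_channel_max <- apply(features, 2, max)
    if (any(per_channel_max <= 0))
      stopf("degenerate channel: zero maximum in channel(s) %s",
            paste(which(per_channel_max <= 0), collapse = ", "))
  }
  out <- sweep(features, 2, per_channel_max, "/")
  out <- pmin(pmax(out, 0), 1)
  list(features = out, per_channel_max = per_channel_max)
}

# Trial stream ids at the raw-sample level: each movement trial together with
# its trailing rest is one stream; leading rest before the first trial is
# stream 0.
stream_ids <- function(stimulus, repetition) {
  Tn <- length(stimulus)
  prev_s <- c(-1L, stimulus[-Tn])
  prev_r <- c(-1L, repetition[-Tn])
  onset <- stimulus > 0L & (prev_s != stimulus | prev_r != repetition)
  cumsum(onset)
}

#' Build a feature sequence from a recording
#'
#' Computes the per-channel RMS envelope and aligns every frame with the
#' joint angles, labels and trial stream at the last raw sample of its RMS
#' window. Features are raw RMS values; unit scaling and mu-law companding
#' are applied later so their parameters can be fitted on training data only.
#'
#' @param rec an [emg_recording()].
#' @param cfg a [preprocess_config()] (the RMS window/hop are converted from
#'   ms using `rec$fs`).
#' @return an object of class `feature_sequence`.
#' @export
feature_sequence <- function(rec, cfg = preprocess_config()) {
  stopifnot(inherits(rec, "emg_recording"))
  window <- max(1L, round(cfg$rms_window_ms * rec$fs / 1000))
  step <- max(1L, round(cfg$rms_step_ms * rec$fs / 1000))
  feats <- rms_envelope(rec$emg, window, step)
  ends <- seq(window, nrow(rec$emg), by = step)
  sid <- stream_ids(rec$stimulus, rec$repetition)
  structure(list(features = feats, angles = rec$angles[ends, , drop = FALSE],
                 frame_end = ends, movement = rec$stimulus[ends],
                 repetition = rec$repetition[ends], stream = sid[ends],
                 segment = sid[ends], rms_window = window, rms_step = step,
                 fs = rec$fs, subject_id = rec$subject_id),
            class = "feature_sequence")
}

subset_sequence <- function(seq, idx, segment) {
  structure(list(features = seq$features[idx, , drop = FALSE],
                 angles = seq$angles[idx, , drop = FALSE],
                 frame_end = seq$frame_end[idx], movement = seq$movement[idx],
                 repetition = seq$repetition[idx], stream = seq$stream[idx],
                 segment = segment, rms_window = seq$rms_window,
                 rms_step = seq$rms_step, fs = seq$fs,
                 subject_id = seq$subject_id),
            class = "feature_sequence")
}

# Frames at the head of a segment whose RMS window still overlaps raw samples
# of the preceding (removed or differently-assigned) frames.
guard_frames <- function(seq) {
  if (seq$rms_step >= seq$rms_window) 0L
  else as.integer(ceiling((seq$rms_window - seq$rms_step) / seq$rms_step))
}

# Phase segments: maximal runs of constant (stimulus, repetition) at the
# frame level -- each movement execution and each rest period is its own
# temporal unit for splitting and folding, so held-out portions contain
# movement dynamics, not only rest.
phase_runs <- function(seq) {
  key <- paste(seq$movement, seq$repetition)
  n <- length(key)
  cumsum(c(TRUE, key[-1] != key[-n]))
}

# Assemble one side of a split: `pieces` is a list of frame-index vectors in
# temporal order. Every piece loses `guard` leading frames -- unless it opens
# the recording -- because the raw samples inside the first RMS windows of a
# piece extend back into frames that belong to the other side (this applies
# across stream boundaries too: a stream's first piece follows the previous
# stream's last piece in raw time).
assemble_side <- function(seq, pieces, guard) {
  keep <- integer(0)
  segs <- integer(0)
  segid <- 0L
  for (i in seq_along(pieces)) {
    p <- pieces[[i]]
    if (length(p) > 0L && p[1] != 1L && guard > 0L)
      p <- p[-seq_len(min(guard, length(p)))]
    if (length(p) == 0L) next
    segid <- segid + 1L
    keep <- c(keep, p)
    segs <- c(segs, rep(segid, length(p)))
  }
  subset_sequence(seq, keep, segs)
}

#' Leakage-safe temporal train/test split
#'
#' Within each phase segment -- each movement execution and each rest period
#' separately -- the first `ratio` of frames form the training set and the
#' remainder the test set, so held-out data contain movement dynamics (the
#' release phase of every trial) and not only rest. Guard frames whose RMS
#' windows overlap raw samples used by the other side are excluded, and
#' model windows are never formed across a boundary, so no test window
#' shares raw samples with any training window.
#'
#' @param seq a [feature_sequence()].
#' @param ratio training fraction, in (0, 1).
#' @param L model window length in frames (used only to warn when a test
#'   piece cannot yield a single window).
#' @return list with `train` and `test` feature sequences.
#' @export
split_train_test <- function(seq, ratio = 0.7, L = 200L) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie strictly in (0, 1)")
  guard <- guard_frames(seq)
  runs <- phase_runs(seq)
  tr_pieces <- list(); te_pieces <- list()
  for (s in unique(runs)) {
    idx <- which(runs == s)
    ntr <- floor(ratio * length(idx))
    tr_pieces <- c(tr_pieces, list(idx[seq_len(ntr)]))
    te <- if (ntr < length(idx)) idx[(ntr + 1):length(idx)] else integer(0)
    if (length(te) - guard < L)
      warnf("segment %s: test piece too short for a window of %d frames; skipped",
            s, L)
    te_pieces <- c(te_pieces, list(te))
  }
  list(train = assemble_side(seq, tr_pieces, guard),
       test = assemble_side(seq, te_pieces, guard))
}

#' Leakage-safe split by repetition
#'
#' Assigns whole trials to the two sides: for each movement, the first
#' `round(ratio * n_reps)` repetitions (with their trailing rest) form the
#' training set and the remaining repetitions the test set. Every movement
#' phase — onset, hold, release, rest — is represented on both sides, with
#' held-out repetitions providing unseen realizations; the same guard-frame
#' rule as [split_train_test()] removes raw-sample overlap at the trial
#' boundaries.
#'
#' @inheritParams split_train_test
#' @return list with `train` and `test` feature sequences.
#' @export
split_by_repetition <- function(seq, ratio = 0.7, L = 200L) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (ratio <= 0 || ratio >= 1) stopf("ratio must lie strictly in (0, 1)")
  guard <- guard_frames(seq)
  reps <- sort(unique(seq$repetition[seq$repetition > 0]))
  if (length(reps) < 2) stopf("need at least 2 repetitions to split")
  n_train <- max(1L, min(length(reps) - 1L, round(ratio * length(reps))))
  train_reps <- reps[seq_len(n_train)]
  # a trial stream (movement + trailing rest) belongs to its repetition
  rep_of_stream <- tapply(seq$repetition, seq$stream, max)
  in_train <- seq$repetition %in% train_reps |
    (seq$movement == 0 &
       rep_of_stream[as.character(seq$stream)] %in% train_reps)
  pieces_of <- function(mask) {
    idx <- which(mask)
    if (length(idx) == 0) return(list())
    split(idx, cumsum(c(1L, diff(idx) != 1L)))
  }
  list(train = assemble_side(seq, pieces_of(in_train), guard),
       test = assemble_side(seq, pieces_of(!in_train), guard))
}

#' Temporal k-fold partition
#'
#' Each phase segment (movement execution or rest period) is cut into `k`
#' contiguous temporal pieces; fold i takes piece i of every segment as its
#' test set and the remaining frames as training, with the same guard-frame
#' rule as [split_train_test()]. Fold 1 covers movement onset, middle folds
#' the hold phase, late folds the release.
#'
#' @param seq a [feature_sequence()].
#' @param k number of folds (>= 2).
#' @param L model window length in frames.
#' @return list of `k` lists, each with `train` and `test`.
#' @export
make_folds <- function(seq, k = 5L, L = 200L) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (k < 2) stopf("k must be >= 2")
  guard <- guard_frames(seq)
  runs <- phase_runs(seq)
  cuts <- lapply(unique(runs), function(s) {
    idx <- which(runs == s)
    n <- length(idx)
    if (n < k) stopf("k = %d exceeds the %d usable frames of segment %s", k, n, s)
    bounds <- floor(seq(0, n, length.out = k + 1))
    lapply(seq_len(k), function(i) idx[(bounds[i] + 1):bounds[i + 1]])
  })
  lapply(seq_len(k), function(i) {
    te_pieces <- list()
    tr_pieces <- list()
    for (sc in cuts) {
      te_pieces <- c(te_pieces, list(sc[[i]]))
      before <- if (i > 1L) sort(unlist(sc[seq_len(i - 1L)])) else integer(0)
      after <- if (i < k) sort(unlist(sc[(i + 1L):k])) else integer(0)
      if (length(before)) tr_pieces <- c(tr_pieces, list(before))
      if (length(after)) tr_pieces <- c(tr_pieces, list(after))
    }
    list(train = assemble_side(seq, tr_pieces, guard),
         test = assemble_side(seq, te_pieces, guard))
  })
}

#' Cut a feature sequence into model windows
#'
#' Sliding windows of `L` consecutive frames are formed within each
#' contiguous segment (never across a split or trial boundary); the target of
#' a window is the angle vector at its last frame. Segments shorter than `L`
#' are skipped with a warning.
#'
#' @param seq a [feature_sequence()].
#' @param L window length, frames.
#' @param stride hop between window starts, frames.
#' @return an object of class `windowed_dataset` with elements `features`
#'   (the frame matrix), `starts` (window start rows), `y` (targets,
#'   degrees), `L`, and `meta` (per-window provenance with the raw-sample
#'   span covered by each window).
#' @export
make_windows <- function(seq, L = 200L, stride = 1L) {
  stopifnot(inherits(seq, "feature_sequence"))
  if (L < 1 || stride < 1) stopf("L and stride must be >= 1")
  runs <- rle(seq$segment)
  offs <- cumsum(c(0, runs$lengths))
  starts <- integer(0)
  for (i in seq_along(runs$lengths)) {
    n <- runs$lengths[i]
    if (n < L) {
      warnf("segment %s has %d < L = %d frames; skipped", runs$values[i], n, L)
      next
    }
    starts <- c(starts, offs[i] + seq(1L, n - L + 1L, by = stride))
  }
  ends <- starts + L - 1L
  meta <- data.frame(
    subject = rep(seq$subject_id, length(starts)),
    movement = seq$movement[ends], repetition = seq$repetition[ends],
    segment = seq$segment[ends],
    raw_start = seq$frame_end[starts] - seq$rms_window + 1L,
    raw_end = seq$frame_end[ends])
  structure(list(features = seq$features, starts = starts,
                 y = seq$angles[ends, , drop = FALSE], L = as.integer(L),
                 stride = as.integer(stride), frame_end = seq$frame_end,
                 meta = meta),
            class = "windowed_dataset")
}

#' @export
print.windowed_dataset <- function(x, ...) {
  cat(sprintf("<windowed_dataset: %d windows of %d frames x %d channels>\n",
              length(x$starts), x$L, ncol(x$features)))
  invisible(x)
}

#' Per-joint target scaler
#'
#' Centers by the per-joint mean and scales by the per-joint standard
#' deviation (floored at 1e-6), fitted on training targets only; predictions
#' are inverted back to degrees before any metric is computed.
#'
#' @param train_y `n x J` training target matrix, degrees.
#' @return an object of class `target_scaler` with `center` and `scale`.
#' @export
fit_target_scaler <- function(train_y) {
  train_y <- as.matrix(train_y)
  if (nrow(train_y) == 0) stopf("empty training targets")
  structure(list(center = colMeans(train_y),
                 scale = pmax(apply(train_y, 2, stats::sd), 1e-6)),
            class = "target_scaler")
}

#' @rdname fit_target_scaler
#' @param scaler a `target_scaler`.
#' @param y matrix of targets (degrees) or predictions (scaled units).
#' @export
apply_target_scaler <- function(scaler, y) {
  sweep(sweep(as.matrix(y), 2, scaler$center, "-"), 2, scaler$scale, "/")
}

#' @rdname fit_target_scaler
#' @export
invert_target_scaler <- function(scaler, y) {
  sweep(sweep(as.matrix(y), 2, scaler$scale, "*"), 2, scaler$center, "+")
}
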