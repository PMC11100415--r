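# Shared fixtures: everything is generated in code at test time.

# A reduced acquisition protocol for unit tests: full trial semantics
# (movement + rest, labels, synergy mixing) at a fraction of the samples.
tiny_synth <- function(n_movements = 2L, n_reps = 2L, fs = 200,
                       move_dur = 2, rest_dur = 1, snr_db = 20, seed = 5L) {
  synth_config(n_movements = n_movements, n_reps = n_reps, fs = fs,
               move_dur = move_dur, rest_dur = rest_dur, snr_db = snr_db,
               seed = seed)
}

# Preprocessing sized to the tiny protocol: 50 ms RMS window, 10 ms hop,
# 20-frame model windows.
tiny_pre <- function(L = 20L, train_stride = 5L, eval_stride = 2L) {
  preprocess_config(rms_window_ms = 50, rms_step_ms = 10, L = L,
                    train_stride = train_stride, eval_stride = eval_stride)
}

# Frame-level RMS oracle: explicit loop over frames and channels.
rms_oracle <- function(emg, window, step) {
  ends <- seq(window, nrow(emg), by = step)
  out <- matrix(0, length(ends), ncol(emg))
  for (k in seq_along(ends)) {
    for (c in seq_len(ncol(emg))) {
      seg <- emg[(ends[k] - window + 1):ends[k], c]
      out[k, c] <- sqrt(mean(seg^2))
    }
  }
  out
}

# Raw-sample index set underlying one window of a windowed_dataset.
window_raw_samples <- function(ds, i, rms_window, rms_step) {
  frames <- ds$starts[i]:(ds$starts[i] + ds$L - 1L)
  ends <- ds$frame_end[frames]
  unique(unlist(lapply(ends, function(e) (e - rms_window + 1L):e)))
}

expect_no_raw_overlap <- function(train_ds, test_ds, rms_window, rms_step) {
  tr <- unique(unlist(lapply(seq_along(train_ds$starts), function(i)
    window_raw_samples(train_ds, i, rms_window, rms_step))))
  te <- unique(unlist(lapply(seq_along(test_ds$starts), function(i)
    window_raw_samples(test_ds, i, rms_window, rms_step))))
  expect_length(intersect(tr, te), 0)
}

# Independent two-pass metric oracles, coded directly from the definitions.
pcc_oracle <- function(e, r) {
  de <- e - mean(e); dr <- r - mean(r)
  sum(de * dr) / sqrt(sum(de^2) * sum(dr^2))
}
r2_oracle <- function(e, r) 1 - sum((e - r)^2) / sum((r - mean(r))^2)
rmse_oracle <- function(e, r) sqrt(sum((e - r)^2) / length(e))
nrmse_oracle <- function(e, r) rmse_oracle(e, r) / (max(r) - min(r))
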