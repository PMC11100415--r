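#' Configuration of the synthetic sEMG / kinematics generator
#'
#' The generator emulates the acquisition protocol of a Ninapro DB2-style
#' recording session: 12 surface EMG channels at 2 kHz synchronized with 10
#' finger-joint angle traces, 6 movements x 6 repetitions, each trial 5 s of
#' movement followed by 3 s of rest. Movements drive a small set of latent
#' "synergy" activations with smooth rise-plateau-fall profiles; fixed,
#' seeded nonnegative mixing matrices map synergies to EMG-channel amplitude
#' envelopes and (after 4 Hz low-pass filtering) to joint angles. EMG is a
#' zero-mean 20-450 Hz band-limited Gaussian carrier amplitude-modulated by
#' (noise floor + activation); `snr_db` sets the modulation depth over the
#' floor.
#'
#' @param n_channels EMG channels.
#' @param n_joints joint-angle traces.
#' @param n_movements distinct movement classes.
#' @param n_reps repetitions per movement.
#' @param fs sampling rate, Hz.
#' @param move_dur,rest_dur movement / rest durations per trial, seconds.
#' @param snr_db envelope modulation over the noise floor, dB.
#' @param n_synergies latent activation count.
#' @param act_scale global activation multiplier; 0 gives a rest-only
#'   recording (angles flat at their baseline, EMG pure noise floor).
#' @param tonic_level amplitude of the low-frequency tonic (postural)
#'   synergy activity present throughout the recording, as a fraction of
#'   the movement activation peak. Real resting hands are never perfectly
#'   still: residual muscle tone produces small, slow, EMG-coupled joint
#'   fluctuations, and without them the rest phase would be kinematically
#'   degenerate (constant angles). Scaled by `act_scale` like the movement
#'   drive.
#' @param joint_min,joint_max per-joint angle range, degrees (scalars are
#'   recycled).
#' @param seed integer seed; generation is a pure function of
#'   `(config, subject_id)`.
#' @return an object of class `synth_config`.
#' @export
synth_config <- function(n_channels = 12L, n_joints = 10L, n_movements = 6L,
                         n_reps = 6L, fs = 2000, move_dur = 5, rest_dur = 3,
                         snr_db = 20, n_synergies = 4L, act_scale = 1,
                         tonic_level = 0.15, joint_min = 0, joint_max = 90,
                         seed = 1L) {
  if (any(c(n_channels, n_joints, n_movements, n_reps, n_synergies) < 1))
    stopf("all counts must be >= 1")
  if (fs <= 0 || move_dur <= 0 || rest_dur < 0)
    stopf("fs and move_dur must be positive, rest_dur nonnegative")
  structure(list(n_channels = as.integer(n_channels),
                 n_joints = as.integer(n_joints),
                 n_movements = as.integer(n_movements),
                 n_reps = as.integer(n_reps), fs = fs, move_dur = move_dur,
                 rest_dur = rest_dur, snr_db = snr_db,
                 n_synergies = as.integer(n_synergies), act_scale = act_scale,
                 tonic_level = tonic_level,
                 joint_min = rep_len(joint_min, n_joints),
                 joint_max = rep_len(joint_max, n_joints),
                 seed = as.integer(seed)),
            class = "synth_config")
}

#' Construct an EMG recording container
#'
#' Synchronized multichannel EMG, joint angles and movement/repetition labels
#' at a common sampling rate. Label 0 marks rest in both label vectors.
#'
#' @param emg `T x n_channels` matrix, arbitrary units.
#' @param angles `T x n_joints` matrix, degrees.
#' @param stimulus,repetition integer vectors of length `T`; 0 = rest.
#' @param fs sampling rate, Hz.
#' @param subject_id identifier.
#' @return an object of class `emg_recording`.
#' @export
emg_recording <- function(emg, angles, stimulus, repetition, fs, subject_id) {
  emg <- as.matrix(emg); angles <- as.matrix(angles)
  Tn <- nrow(emg)
  if (nrow(angles) != Tn || length(stimulus) != Tn || length(repetition) != Tn)
    stopf("emg, angles, stimulus and repetition must share the same length")
  if (!all(is.finite(angles))) stopf("angles must be finite")
  structure(list(emg = emg, angles = angles,
                 stimulus = as.integer(stimulus),
                 repetition = as.integer(repetition),
                 fs = fs, subject_id = subject_id),
            class = "emg_recording")
}

#' @export
print.emg_recording <- function(x, ...) {
  cat(sprintf(
    "<emg_recording subject %s: %d samples @ %g Hz, %d EMG ch, %d joints, %d movements>\n",
    x$subject_id, nrow(x$emg), x$fs, ncol(x$emg), ncol(x$angles),
    length(setdiff(unique(x$stimulus), 0L))))
  invisible(x)
}

# Sparse nonnegative synergy weight vector of movement m; pure in (config, m).
movement_weights <- function(movement_id, config) {
  m <- as.integer(movement_id)
  if (is.na(m) || m < 1L || m > config$n_movements)
    stopf("unknown movement_id '%s' (1..%d)", movement_id, config$n_movements)
  S <- config$n_synergies
  with_seed(derive_seed(config$seed, 1000L + m), {
    w <- stats::runif(S, 0.3, 1)
    if (S > 1) {
      nzero <- min(S - 1L, max(0L, floor(S / 2)))
      w[sample.int(S, nzero)] <- 0
    }
    w / max(w)
  })
}

#' Latent activation profile of one movement trial
#'
#' Smooth rise-plateau-fall envelope (raised-cosine ramps over the first and
#' last 20% of the trial) times a movement-specific sparse synergy weight
#' vector; values lie in `[0, 1]` and start and end at zero.
#'
#' @param movement_id movement class in `1..config$n_movements`.
#' @param duration_s trial duration, seconds (> 0).
#' @param fs sampling rate, Hz.
#' @param config a [synth_config()].
#' @return `T_move x n_synergies` matrix.
#' @export
activation_profile <- function(movement_id, duration_s, fs, config) {
  if (duration_s <= 0) stopf("duration_s must be positive")
  w <- movement_weights(movement_id, config)
  Tm <- round(duration_s * fs)
  if (Tm < 2) stopf("duration_s * fs must span at least 2 samples")
  tt <- (seq_len(Tm) - 1) / (Tm - 1)
  ramp <- 0.2
  env <- rep(1, Tm)
  up <- tt < ramp
  down <- tt > 1 - ramp
  env[up] <- 0.5 * (1 - cos(pi * tt[up] / ramp))
  env[down] <- 0.5 * (1 - cos(pi * (1 - tt[down]) / ramp))
  outer(env, w)
}

#' Generate a synthetic recording
#'
#' Lays out `n_movements x n_reps` trials (movement-major, each `move_dur` s
#' of movement followed by `rest_dur` s of rest), drives per-movement synergy
#' activations through fixed seeded nonnegative mixing matrices, and renders
#' EMG as amplitude-modulated band-limited noise and angles as an affine map
#' of the 4 Hz low-pass-filtered joint drive into each joint's range.
#' Bit-identical for repeated calls with the same `(config, subject_id)`.
#'
#' @param config a [synth_config()].
#' @param subject_id integer-like identifier; different subjects share the
#'   trial structure but have different mixing matrices.
#' @return an [emg_recording()].
#' @export
generate_recording <- function(config, subject_id = 1L) {
  stopifnot(inherits(config, "synth_config"))
  fs <- config$fs
  Tm <- round(config$move_dur * fs)
  Tr <- round(config$rest_dur * fs)
  Ttrial <- Tm + Tr
  M <- config$n_movements; R <- config$n_reps; S <- config$n_synergies
  Tn <- M * R * Ttrial
  sid <- as.integer(subject_id)

  # subject-specific nonnegative mixing matrices
  mix <- with_seed(derive_seed(config$seed, 7919L * sid), {
    list(emg = matrix(stats::runif(S * config$n_channels, 0.1, 1), S),
         joint = matrix(stats::runif(S * config$n_joints, 0.1, 1), S))
  })

  act <- matrix(0, Tn, S)
  stimulus <- integer(Tn)
  repetition <- integer(Tn)
  off <- 0L
  for (m in seq_len(M)) {
    prof <- activation_profile(m, config$move_dur, fs, config)
    for (r in seq_len(R)) {
      idx <- off + seq_len(Tm)
      act[idx, ] <- prof
      stimulus[idx] <- m
      repetition[idx] <- r
      off <- off + Ttrial
    }
  }
  # low-amplitude tonic (postural) synergy activity: smooth band-limited
  # stochastic muscle tone present in movement and rest alike
  if (config$tonic_level > 0) {
    tone <- with_seed(derive_seed(config$seed, 7717L * sid + 3L), {
      z <- matrix(stats::rnorm(Tn * S), Tn, S)
      lp_t <- signal::butter(2, min(1.5 / (fs / 2), 0.9), type = "low")
      z <- apply(z, 2, function(u) as.numeric(signal::filter(lp_t, u)))
      z <- sweep(z, 2, apply(z, 2, stats::sd), "/")    # unit variance
      pmin(pmax(0.5 + z / 4, 0), 1) * config$tonic_level
    })
    act <- act + tone
  }
  act <- act * config$act_scale

  chan_act <- act %*% mix$emg                    # T x channels, >= 0
  cmax <- apply(chan_act, 2, max)
  chan_act <- sweep(chan_act, 2, pmax(cmax, 1e-12), "/")
  gain <- 10^(config$snr_db / 20)
  contribution <- gain * chan_act
  contribution[chan_act == 0] <- 0               # keeps snr_db = Inf finite
  amp <- 1 + contribution                        # noise floor 1

  # 20-450 Hz surface-EMG band, clamped below Nyquist for low-rate configs
  hi <- min(450, 0.92 * fs / 2)
  lo <- min(20, hi / 4)
  bp <- signal::butter(4, c(lo, hi) / (fs / 2), type = "pass")
  emg <- with_seed(derive_seed(config$seed, 104729L * sid + 1L), {
    carrier <- matrix(stats::rnorm(Tn * config$n_channels), Tn)
    apply(carrier, 2, function(x) as.numeric(signal::filter(bp, x)))
  })
  emg <- emg * amp

  joint_act <- act %*% mix$joint
  lp <- signal::butter(2, min(4 / (fs / 2), 0.99), type = "low")
  joint_act <- apply(joint_act, 2, function(x)
    as.numeric(signal::filtfilt(lp, x)))
  jmax <- pmax(apply(joint_act, 2, max), 1e-12)
  angles <- sweep(joint_act, 2, jmax, "/")
  angles <- pmin(pmax(angles, 0), 1)             # filter ringing guard
  angles <- sweep(sweep(angles, 2, config$joint_max - config$joint_min, "*"),
                  2, config$joint_min, "+")

  emg_recording(emg, angles, stimulus, repetition, fs, sid)
}

#' Write / read a recording archive
#'
#' Persists one recording as a single file using R's native serialization,
#' with the datasets `emg`, `angles`, `stimulus`, `repetition` and the
#' attributes `fs` and `subject_id`.
#'
#' @param rec an [emg_recording()].
#' @param path file path (conventionally `.rds`).
#' @export
write_recording <- function(rec, path) {
  stopifnot(inherits(rec, "emg_recording"))
  saveRDS(unclass(rec), path)
  invisible(path)
}

#' @rdname write_recording
#' @export
read_recording <- function(path) {
  obj <- readRDS(path)
  emg_recording(obj$emg, obj$angles, obj$stimulus, obj$repetition, obj$fs,
                obj$subject_id)
}
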