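#' Default glove sensor indices for the 10 regression targets
#'
#' The 10 estimated joints are the metacarpophalangeal (MCP) and proximal
#' interphalangeal (PIP, thumb: interphalangeal) flexion sensors of a
#' 22-sensor CyberGlove II layout, 1-based. The exact sensor subset is a
#' configuration choice; this default follows a common layout with thumb
#' MP/IP at sensors 2-3 and the four fingers' MCP/PIP pairs at 5-6, 8-9,
#' 11-12 and 14-15.
#'
#' @return integer vector of length 10 (values in 1..22).
#' @export
default_joint_indices <- function() c(2L, 3L, 5L, 6L, 8L, 9L, 11L, 12L, 14L, 15L)

#' Load a Ninapro DB2-style subject file
#'
#' Reads a per-subject `.mat` file containing 12-channel sEMG at 2 kHz and
#' the 22-sensor glove trace resampled to the same rate, plus movement and
#' repetition label vectors. The refined labels (`restimulus`,
#' `rerepetition`) are used when present, falling back to `stimulus` /
#' `repetition`. Signal values are passed through untouched; all filtering
#' and normalization belongs to the preprocessing stage.
#'
#' @param path `.mat` file path.
#' @param joint_indices glove sensor columns (1-based, in 1..22) kept as
#'   regression targets.
#' @param n_channels expected EMG channel count.
#' @return an [emg_recording()].
#' @export
load_ninapro_db2 <- function(path, joint_indices = default_joint_indices(),
                             n_channels = 12L) {
  if (anyDuplicated(joint_indices) || any(joint_indices < 1))
    stopf("joint_indices must be unique positive sensor numbers")
  vars <- read_mat(path)
  need <- function(nm, alt = NULL) {
    if (!is.null(vars[[nm]])) return(vars[[nm]])
    if (!is.null(alt) && !is.null(vars[[alt]])) return(vars[[alt]])
    stopf("format error: '%s' is missing field '%s'", path,
          paste(c(nm, alt), collapse = "' / '"))
  }
  emg <- need("emg")
  glove <- need("glove")
  stim <- need("restimulus", "stimulus")
  rep_ <- need("rerepetition", "repetition")
  if (ncol(emg) != n_channels)
    stopf("format error: expected %d EMG channels, found %d", n_channels,
          ncol(emg))
  if (any(joint_indices > ncol(glove)))
    stopf("joint_indices exceed the %d glove sensors", ncol(glove))
  emg_recording(emg, glove[, joint_indices, drop = FALSE],
                as.integer(stim), as.integer(rep_), fs = 2000,
                subject_id = sub("\\.mat$", "", basename(path)))
}

#' Restrict a recording to selected movements
#'
#' Keeps, in temporal order, every sample of every trial whose movement id is
#' in `movement_ids`, together with the rest samples immediately following
#' each selected trial. Labels are preserved; samples are never duplicated or
#' reordered.
#'
#' @param rec an [emg_recording()].
#' @param movement_ids non-empty vector of movement labels.
#' @return an [emg_recording()] containing the selected samples.
#' @export
select_movements <- function(rec, movement_ids) {
  stopifnot(inherits(rec, "emg_recording"))
  if (length(movement_ids) == 0) stopf("movement_ids must be non-empty")
  sid <- stream_ids(rec$stimulus, rec$repetition)
  stream_mov <- tapply(rec$stimulus, sid, function(s) max(s))
  keep_streams <- names(stream_mov)[stream_mov %in% movement_ids]
  keep <- sid %in% as.integer(keep_streams) & sid > 0
  if (!any(keep))
    stopf("empty selection: no samples with stimulus in {%s}",
          paste(movement_ids, collapse = ", "))
  emg_recording(rec$emg[keep, , drop = FALSE],
                rec$angles[keep, , drop = FALSE],
                rec$stimulus[keep], rec$repetition[keep], rec$fs,
                rec$subject_id)
}

#' Write / read a tidy metrics table
#'
#' Persists an evaluation report as a tidy CSV with columns
#' `subject, model, joint, metric, value, fold`; an empty report gives a
#' header-only file. `read_metrics_table()` restores it losslessly.
#'
#' @param report an `eval_report` data frame (possibly zero rows).
#' @param path CSV path.
#' @export
write_metrics_table <- function(report, path) {
  cols <- c("subject", "model", "joint", "metric", "value", "fold")
  if (nrow(report) == 0)
    report <- data.frame(subject = character(), model = character(),
                         joint = integer(), metric = character(),
                         value = numeric(), fold = character())
  utils::write.csv(report[, cols], path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_metrics_table
#' @export
read_metrics_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  structure(df, class = c("eval_report", "data.frame"))
}
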