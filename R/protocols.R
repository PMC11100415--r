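#' Experiment specification
#'
#' Bundles everything needed to reproduce an experiment: the model
#' configurations, the data source (a [synth_config()] plus subject ids, or
#' a list of [emg_recording()]s), and the preprocessing and training
#' configurations.
#'
#' @param models list of [fit_config()] / [baseline_config()] objects.
#' @param synth a [synth_config()] used to generate one recording per entry
#'   of `subjects` (ignored when `recordings` is given).
#' @param subjects vector of subject ids for the generator.
#' @param recordings optional list of [emg_recording()]s (overrides the
#'   generator).
#' @param pre a [preprocess_config()].
#' @param train a [train_config()].
#' @return an object of class `experiment_spec`.
#' @export
experiment_spec <- function(models, synth = synth_config(), subjects = 1L,
                            recordings = NULL, pre = preprocess_config(),
                            train = train_config()) {
  if (length(models) == 0) stopf("at least one model is required")
  for (m in models) stopifnot(inherits(m, "model_config"))
  structure(list(models = models, synth = synth, subjects = subjects,
                 recordings = recordings, pre = pre, train = train),
            class = "experiment_spec")
}

#' Fast desk-scale profile
#'
#' Preprocessing and training settings sized for a single CPU: 20 ms RMS hop
#' (50 Hz envelope), 64-frame windows (1.28 s of context, short enough that
#' the held-out portion of each movement segment fits complete windows), and
#' 15 training epochs (30 for the LSTM family). The model architectures are
#' unchanged; the LSTM and TCN families train for twice the epochs, as
#' they converge more slowly. See the methods vignette for the rationale.
#'
#' @return list with elements `pre` and `train`.
#' @export
fast_profile <- function() {
  list(pre = preprocess_config(rms_step_ms = 20, L = 64L, train_stride = 10L,
                               eval_stride = 1L),
       train = train_config(epochs = 15L, epochs_lstm = 30L, epochs_tcn = 30L))
}

#' Standard model set
#'
#' The four model configurations (FIT and the three baselines) instantiated
#' for a given window length and channel/joint count, plus optionally the
#' oracle stub.
#'
#' @param L window length, frames.
#' @param in_channels,n_joints input/output dimensions.
#' @param seed weight-init seed shared by all configurations.
#' @param families subset of `c("fit", "tcn", "bert", "lstm", "oracle")`.
#' @return named list of model configurations.
#' @export
make_model_set <- function(L = 200L, in_channels = 12L, n_joints = 10L,
                           seed = 1L,
                           families = c("fit", "tcn", "bert", "lstm")) {
  cfgs <- lapply(families, function(f) {
    if (f == "fit")
      fit_config(in_channels = in_channels, L = L, n_joints = n_joints,
                 seed = seed)
    else
      baseline_config(f, in_channels = in_channels, n_joints = n_joints,
                      L = L, seed = seed)
  })
  names(cfgs) <- families
  cfgs
}

spec_split <- function(seq, pre) {
  if ((pre$split_by %||% "repetition") == "repetition")
    split_by_repetition(seq, pre$split_ratio, pre$L)
  else split_train_test(seq, pre$split_ratio, pre$L)
}

spec_recordings <- function(spec) {
  recs <- spec$recordings %||%
    lapply(spec$subjects, function(s) generate_recording(spec$synth, s))
  if (is.null(names(recs)))
    names(recs) <- vapply(recs, function(r) as.character(r$subject_id), "")
  recs
}

# Normalize features (train-fitted unit maxima + mu-law), window both sides,
# and fit the target scaler on the training windows.
prepare_split <- function(train_seq, test_seq, pre, maxima = NULL,
                          scaler = NULL) {
  su <- scale_to_unit(train_seq$features, maxima)
  train_seq$features <- mu_law_normalize(su$features, pre$mu)
  wtrain <- make_windows(train_seq, pre$L, pre$train_stride)
  wtest <- NULL
  if (!is.null(test_seq)) {
    st <- scale_to_unit(test_seq$features, su$per_channel_max)
    test_seq$features <- mu_law_normalize(st$features, pre$mu)
    wtest <- make_windows(test_seq, pre$L, pre$eval_stride)
  }
  scaler <- scaler %||% fit_target_scaler(wtrain$y)
  wtrain$y_degrees <- wtrain$y
  wtrain$y <- apply_target_scaler(scaler, wtrain$y)
  list(train = wtrain, test = wtest, scaler = scaler,
       maxima = su$per_channel_max)
}

train_and_eval <- function(cfg, prep, train_cfg, subject, fold) {
  model <- build_model(cfg)
  tr <- train_model(model, prep$train, train_cfg)
  pred <- predict_model(tr$model, prep$test)
  pred_deg <- if (cfg$family == "oracle") prep$test$y
              else invert_target_scaler(prep$scaler, pred)
  evaluate(pred_deg, prep$test$y, subject = subject, model = cfg$family,
           fold = fold)
}

#' Within-subject experiment (7:3 split)
#'
#' For every subject: preprocess, split 7:3 (by repetition by default; see
#' [preprocess_config()]), train every model on the training windows and
#' evaluate on that subject's test windows.
#'
#' @param spec an [experiment_spec()].
#' @param verbose print progress.
#' @return an `eval_report` data frame (fold = `"7:3"`).
#' @export
run_within_subject <- function(spec, verbose = FALSE) {
  recs <- spec_recordings(spec)
  reports <- list()
  for (si in seq_along(recs)) {
    rec <- recs[[si]]
    seq <- feature_sequence(rec, spec$pre)
    sp <- spec_split(seq, spec$pre)
    prep <- prepare_split(sp$train, sp$test, spec$pre)
    for (cfg in spec$models) {
      if (verbose)
        message(sprintf("subject %s / model %s", rec$subject_id, cfg$family))
      reports[[length(reports) + 1]] <-
        train_and_eval(cfg, prep, spec$train, rec$subject_id, "7:3")
    }
  }
  structure(do.call(rbind, reports), class = c("eval_report", "data.frame"))
}

#' Cross-subject experiment (merged training sets)
#'
#' Pools every subject's training windows, trains each model once, and
#' evaluates both on the pooled test set (reported as subject `"ALL"`) and
#' on each subject's own test set; the per-subject average ("AVG") is the
#' mean of the per-subject rows, available via [report_subject_means()].
#'
#' @inheritParams run_within_subject
#' @return an `eval_report` data frame (fold = `"cross"`).
#' @export
run_cross_subject <- function(spec, verbose = FALSE) {
  recs <- spec_recordings(spec)
  if (length(recs) < 2) stopf("cross-subject protocol needs >= 2 subjects")
  splits <- lapply(recs, function(rec) {
    seq <- feature_sequence(rec, spec$pre)
    spec_split(seq, spec$pre)
  })
  # pooled per-channel maxima and target scaler, fitted on training data only
  maxima <- Reduce(pmax, lapply(splits, function(s) {
    apply(s$train$features, 2, max)
  }))
  preps <- lapply(splits, function(s)
    prepare_split(s$train, s$test, spec$pre, maxima = maxima))
  pooled_y <- do.call(rbind, lapply(preps, function(p) p$train$y_degrees))
  scaler <- fit_target_scaler(pooled_y)
  train_all <- concat_windowed(lapply(preps, `[[`, "train"))
  train_all$y <- apply_target_scaler(scaler, train_all$y_degrees)
  test_all <- concat_windowed(lapply(preps, `[[`, "test"))
  reports <- list()
  for (cfg in spec$models) {
    if (verbose) message(sprintf("cross-subject / model %s", cfg$family))
    model <- build_model(cfg)
    tr <- train_model(model, train_all, spec$train)
    for (nm in c("ALL", names(recs))) {
      ds <- if (nm == "ALL") test_all else preps[[nm]]$test
      pred <- predict_model(tr$model, ds)
      pred_deg <- if (cfg$family == "oracle") ds$y
                  else invert_target_scaler(scaler, pred)
      reports[[length(reports) + 1]] <-
        evaluate(pred_deg, ds$y, subject = nm, model = cfg$family,
                 fold = "cross")
    }
  }
  structure(do.call(rbind, reports), class = c("eval_report", "data.frame"))
}

concat_windowed <- function(ds_list) {
  offs <- cumsum(c(0, vapply(ds_list, function(d) nrow(d$features), 0)))
  starts <- unlist(lapply(seq_along(ds_list), function(i)
    ds_list[[i]]$starts + offs[i]))
  out <- ds_list[[1]]
  out$features <- do.call(rbind, lapply(ds_list, `[[`, "features"))
  out$starts <- starts
  out$y <- do.call(rbind, lapply(ds_list, `[[`, "y"))
  yd <- lapply(ds_list, `[[`, "y_degrees")
  if (!any(vapply(yd, is.null, TRUE))) out$y_degrees <- do.call(rbind, yd)
  out$frame_end <- unlist(lapply(ds_list, `[[`, "frame_end"))
  out$meta <- do.call(rbind, lapply(ds_list, `[[`, "meta"))
  out
}

#' Temporal k-fold experiment
#'
#' Runs [make_folds()] per subject (fold 1 = movement onset), trains and
#' evaluates every model on each fold, and appends the 7:3 split as an extra
#' row family, mirroring the fold-table layout (rows fold1..foldk plus 7:3).
#'
#' @inheritParams run_within_subject
#' @param k fold count.
#' @return an `eval_report` data frame with fold labels `fold1..foldk, 7:3`.
#' @export
run_kfold <- function(spec, k = NULL, verbose = FALSE) {
  k <- k %||% spec$pre$k_folds
  recs <- spec_recordings(spec)
  reports <- list()
  for (rec in recs) {
    seq <- feature_sequence(rec, spec$pre)
    folds <- make_folds(seq, k, spec$pre$L)
    for (f in seq_len(k)) {
      prep <- prepare_split(folds[[f]]$train, folds[[f]]$test, spec$pre)
      for (cfg in spec$models) {
        if (verbose)
          message(sprintf("subject %s / fold %d / %s", rec$subject_id, f,
                          cfg$family))
        reports[[length(reports) + 1]] <-
          train_and_eval(cfg, prep, spec$train, rec$subject_id,
                         paste0("fold", f))
      }
    }
    sp <- spec_split(seq, spec$pre)
    prep <- prepare_split(sp$train, sp$test, spec$pre)
    for (cfg in spec$models)
      reports[[length(reports) + 1]] <-
        train_and_eval(cfg, prep, spec$train, rec$subject_id, "7:3")
  }
  structure(do.call(rbind, reports), class = c("eval_report", "data.frame"))
}

#' Significance analysis across models
#'
#' Builds the paired score matrix for one metric (rows = subjects, averaging
#' each subject's joints, or rows = joints, averaging over subjects), runs
#' the Friedman omnibus test and all pairwise exact Wilcoxon signed-rank
#' tests, and flags significance at `alpha`.
#'
#' @param report an `eval_report` covering >= 2 models.
#' @param metric one of `"pcc"`, `"r2"`, `"rmse"`, `"nrmse"`.
#' @param level pair over `"subject"`s (default) or over `"joint"`s.
#' @param alpha significance threshold.
#' @return an object of class `significance_report`.
#' @export
compare_models <- function(report, metric = "pcc",
                           level = c("subject", "joint"), alpha = 0.05) {
  level <- match.arg(level)
  rep_m <- report[report$metric == metric, , drop = FALSE]
  if (nrow(rep_m) == 0) stopf("no rows with metric '%s'", metric)
  unit <- if (level == "subject") "subject" else "joint"
  agg <- stats::aggregate(stats::reformulate(c(unit, "model"), "value"),
                          rep_m, mean, na.rm = TRUE,
                          na.action = stats::na.pass)
  scores <- tapply(agg$value, list(agg[[unit]], agg$model), mean)
  models <- colnames(scores)
  if (length(models) < 2) stopf("need >= 2 models to compare")
  miss <- which(!is.finite(scores), arr.ind = TRUE)
  if (nrow(miss) > 0)
    stopf("incomplete score matrix: missing %s",
          paste(apply(miss, 1, function(ij)
            sprintf("(%s, %s)", rownames(scores)[ij[1]], models[ij[2]])),
            collapse = ", "))
  fr <- friedman_test(scores)
  pairs <- utils::combn(models, 2)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    res <- tryCatch(wilcoxon_signed_rank(scores[, a], scores[, b]),
                    error = function(e) list(statistic = NA_real_,
                                             p_value = NA_real_,
                                             note = conditionMessage(e)))
    data.frame(model_a = a, model_b = b, statistic = res$statistic,
               p_value = res$p_value,
               significant = isTRUE(res$p_value < alpha),
               note = res$note %||% "")
  }))
  structure(list(metric = metric, level = level, alpha = alpha,
                 scores = scores, friedman = fr, pairwise = pw),
            class = "significance_report")
}

#' @export
print.significance_report <- function(x, ...) {
  cat(sprintf("Significance analysis on %s (paired by %s, alpha = %g)\n",
              x$metric, x$level, x$alpha))
  cat(sprintf("Friedman chi-square = %.4g (df = %d), p = %.4g\n",
              x$friedman$statistic, x$friedman$df, x$friedman$p_value))
  print(x$pairwise, row.names = FALSE)
  invisible(x)
}
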