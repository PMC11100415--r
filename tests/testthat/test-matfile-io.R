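test_that("MAT round trip: write then read preserves numeric matrices", {
  set.seed(51)
  vars <- list(emg = matrix(rnorm(60), 10, 6),
               glove = matrix(runif(50, 0, 90), 10, 5),
               fs = matrix(2000, 1, 1))
  for (comp in c(FALSE, TRUE)) {
    path <- tempfile(fileext = ".mat")
    write_mat(path, vars, compress = comp)
    got <- read_mat(path)
    expect_setequal(names(got), names(vars))
    for (nm in names(vars)) expect_equal(got[[nm]], vars[[nm]])
  }
})

test_that("reader handles files written by an independent implementation", {
  # base64-encoded synthetic subject files produced by scipy.io.savemat
  # (plain v5 and compressed v7); contents are deterministic.
  for (v in c("v5", "v7")) {
    b64 <- paste(readLines(system.file(
      "extdata", sprintf("synthetic_db2_tiny_%s.mat.b64", v),
      package = "fitnet")), collapse = "")
    path <- tempfile(fileext = ".mat")
    writeBin(jsonlite::base64_dec(b64), path)
    vars <- read_mat(path)
    expect_setequal(names(vars),
                    c("emg", "glove", "restimulus", "rerepetition", "fs"))
    expect_equal(dim(vars$emg), c(40, 12))
    expect_equal(dim(vars$glove), c(40, 22))
    expect_equal(vars$fs[1, 1], 2000)
    expect_equal(vars$emg[1, 1], -0.989121)
    expect_equal(vars$glove[6, 3], 15.176981)
    expect_equal(sum(vars$emg), 8.078717, tolerance = 1e-6)
    ref_col <- scan(system.file("extdata", "synthetic_db2_tiny_emg_col1.txt",
                                package = "fitnet"), quiet = TRUE)
    expect_equal(vars$emg[, 1], ref_col, tolerance = 1e-12)
  }
})

test_that("load_ninapro_db2 validates fields and selects joints", {
  cfg <- tiny_synth()
  rec <- generate_recording(cfg, 1)
  glove <- matrix(runif(nrow(rec$emg) * 22, 0, 90), ncol = 22)
  path <- tempfile(fileext = ".mat")
  write_mat(path, list(emg = rec$emg, glove = glove,
                       restimulus = matrix(rec$stimulus, ncol = 1),
                       rerepetition = matrix(rec$repetition, ncol = 1)),
            compress = TRUE)
  idx <- default_joint_indices()
  got <- load_ninapro_db2(path, idx)
  expect_s3_class(got, "emg_recording")
  expect_equal(got$emg, rec$emg)                    # never rescaled
  expect_equal(got$angles, glove[, idx])
  expect_equal(got$stimulus, rec$stimulus)
  expect_equal(got$fs, 2000)
  expect_equal(ncol(got$angles), 10)

  # missing field -> format error naming the field
  path2 <- tempfile(fileext = ".mat")
  write_mat(path2, list(emg = rec$emg,
                        restimulus = matrix(rec$stimulus, ncol = 1),
                        rerepetition = matrix(rec$repetition, ncol = 1)))
  expect_error(load_ninapro_db2(path2), "glove")
  # wrong channel count -> format error
  path3 <- tempfile(fileext = ".mat")
  write_mat(path3, list(emg = rec$emg[, 1:7], glove = glove,
                        restimulus = matrix(rec$stimulus, ncol = 1),
                        rerepetition = matrix(rec$repetition, ncol = 1)))
  expect_error(load_ninapro_db2(path3), "12 EMG channels")
  # falls back to raw labels when refined ones are absent
  path4 <- tempfile(fileext = ".mat")
  write_mat(path4, list(emg = rec$emg, glove = glove,
                        stimulus = matrix(rec$stimulus, ncol = 1),
                        repetition = matrix(rec$repetition, ncol = 1)))
  expect_equal(load_ninapro_db2(path4)$stimulus, rec$stimulus)
})

test_that("synthetic recording round-trips through the .mat layout", {
  cfg <- tiny_synth()
  rec <- generate_recording(cfg, 3)
  glove <- matrix(0, nrow(rec$emg), 22)
  idx <- default_joint_indices()
  glove[, idx] <- rec$angles
  path <- tempfile(fileext = ".mat")
  write_mat(path, list(emg = rec$emg, glove = glove,
                       restimulus = matrix(rec$stimulus, ncol = 1),
                       rerepetition = matrix(rec$repetition, ncol = 1)))
  got <- load_ninapro_db2(path, idx)
  expect_equal(got$emg, rec$emg)
  expect_equal(got$angles, rec$angles)
  expect_equal(got$stimulus, rec$stimulus)
  expect_equal(got$repetition, rec$repetition)
})

test_that("select_movements keeps trials with trailing rest, in order", {
  cfg <- tiny_synth(n_movements = 3L, n_reps = 2L)
  rec <- generate_recording(cfg, 1)
  all_sel <- select_movements(rec, 1:3)
  expect_identical(all_sel, rec)                    # identity case
  one <- select_movements(rec, 2)
  Ttrial <- (cfg$move_dur + cfg$rest_dur) * cfg$fs
  expect_equal(nrow(one$emg), cfg$n_reps * Ttrial)
  expect_setequal(unique(one$stimulus), c(0L, 2L))
  # rest follows each selected trial: first sample is movement onset
  expect_equal(one$stimulus[1], 2L)
  expect_equal(one$stimulus[Ttrial], 0L)
  # order preserved, no duplication: strictly increasing source indices
  sid <- fitnet:::stream_ids(rec$stimulus, rec$repetition)
  src <- which(sid %in% unique(sid[rec$stimulus == 2]))
  expect_equal(one$emg, rec$emg[src, , drop = FALSE])
  expect_error(select_movements(rec, 99), "empty selection")
  expect_error(select_movements(rec, integer(0)), "non-empty")
})

test_that("metrics tables round-trip as tidy CSV", {
  set.seed(52)
  truth <- matrix(rnorm(500, 45, 12), 50, 10)
  rep1 <- evaluate(truth + rnorm(500), truth, subject = 1, model = "fit")
  rep2 <- evaluate(truth + rnorm(500, 0, 4), truth, subject = 1, model = "tcn")
  rep <- rbind(rep1, rep2)
  # 2 models x 10 joints x 4 metrics = 80 rows for one subject and fold
  expect_equal(nrow(rep), 80)
  path <- tempfile(fileext = ".csv")
  write_metrics_table(rep, path)
  got <- read_metrics_table(path)
  expect_equal(got$value, rep$value)
  expect_equal(got$model, rep$model)
  # empty report -> header-only CSV
  path2 <- tempfile(fileext = ".csv")
  write_metrics_table(rep[0, ], path2)
  expect_equal(nrow(read_metrics_table(path2)), 0)
  expect_equal(length(readLines(path2)), 1)
})
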