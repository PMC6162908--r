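test_that("epoch extraction yields round((stop-start)*rate) samples, onset-invariant", {
  rec <- raw_recording(matrix(seq_len(2 * 2000), 2, 2000), 250,
                       events = list(list(onset_sample = 0L, label = 1L),
                                     list(onset_sample = 100L, label = 2L)))
  tr <- extract_epoch(rec, rec$events[[1]], c(4, 6))
  expect_equal(ncol(tr$data), 500)
  tr2 <- extract_epoch(rec, rec$events[[2]], c(4, 6))
  expect_equal(ncol(tr2$data), 500)
  # onset shifts content, not length; half-open interval starts at
  # onset + start*rate (0-based)
  expect_equal(tr2$data[1, 1], rec$signal[1, 100 + 4 * 250 + 1])
  rec100 <- raw_recording(matrix(rnorm(500), 1), 100,
                          events = list(list(onset_sample = 0L, label = 1L)))
  expect_equal(ncol(extract_epoch(rec100, rec100$events[[1]],
                                  c(2, 4))$data), 200)
})

test_that("degenerate or out-of-range epoch windows are rejected", {
  rec <- raw_recording(matrix(rnorm(300), 1), 100,
                       events = list(list(onset_sample = 250L, label = 1L)))
  expect_error(extract_epoch(rec, rec$events[[1]], c(4, 4)), "stop > start")
  expect_error(extract_epoch(rec, rec$events[[1]], c(0, 2)), "outside")
})

test_that("trial container round-trips bit-exactly and validates on write", {
  ts <- make_noise_trialset(seed = 42)
  path <- withr::local_tempfile(fileext = ".trialset")
  write_trialset(ts, path)
  back <- read_trialset(path)
  expect_identical(back$class_set, ts$class_set)
  expect_identical(back$sample_rate_hz, ts$sample_rate_hz)
  for (i in seq_along(ts$trials)) {
    expect_identical(back$trials[[i]]$data, ts$trials[[i]]$data)
    expect_identical(back$trials[[i]]$label, ts$trials[[i]]$label)
    expect_identical(back$trials[[i]]$subject_id, ts$trials[[i]]$subject_id)
  }
  # overwrite is deterministic
  write_trialset(ts, path)
  expect_identical(read_trialset(path)$trials[[1]]$data, ts$trials[[1]]$data)
  # invariant violation caught before writing
  bad <- ts
  bad$trials[[1]]$data <- bad$trials[[1]]$data[, 1:10]
  expect_error(write_trialset(bad, path), "share")
})

test_that("container read rejects missing files and foreign/incomplete schemas", {
  expect_error(read_trialset(file.path(tempdir(), "nope.trialset")),
               "no such file")
  path <- withr::local_tempfile()
  saveRDS(list(format = "something-else"), path)
  expect_error(read_trialset(path), "not a")
  ts <- make_noise_trialset()
  write_trialset(ts, path)
  obj <- readRDS(path)
  obj$class_set <- NULL
  saveRDS(obj, path)
  expect_error(read_trialset(path), "missing required attributes")
})

test_that("trial set invariants are enforced", {
  tr1 <- trial(matrix(rnorm(20), 2, 10), 1L)
  tr2 <- trial(matrix(rnorm(20), 2, 10), 3L)
  expect_error(trial_set(list(tr1, tr2), c(1L, 2L), 250), "class_set")
  expect_error(trial(matrix(c(1, NA), 1, 2), 1L), "non-finite")
  expect_error(trial_set(list(), c(1L), 250), "non-empty")
})

test_that("GDF import reports unreadable inputs as errors", {
  expect_error(import_gdf(file.path(tempdir(), "missing.gdf")),
               "no such file")
  expect_error(import_gdf("whatever.gdf", python = "no-such-python"),
               "no such file|not found")
  bogus <- withr::local_tempfile(fileext = ".gdf")
  writeLines("this is not a gdf file", bogus)
  expect_error(import_gdf(bogus), "failed|format")
})
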