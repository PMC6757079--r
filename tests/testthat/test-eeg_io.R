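test_that("raw_eeg validates its invariants", {
  x <- raw_eeg(matrix(1:20 / 10, nrow = 2), fs = 256)
  expect_s3_class(x, "raw_eeg")
  expect_equal(n_channels(x), 2)
  expect_equal(n_samples(x), 10)
  expect_equal(x$channel_names, c("CH1", "CH2"))

  expect_error(raw_eeg(matrix(1, 1, 1), fs = 0), "positive")
  expect_error(raw_eeg(matrix(1:4, 2), fs = 10, channel_names = c("a", "a")),
               "unique")
  bad <- matrix(rnorm(10), nrow = 2)
  bad[2, 3] <- NaN
  expect_error(raw_eeg(bad, fs = 10), "channel 'CH2' at sample index 3")
})

test_that("matrix format round-trips bit-exactly with metadata", {
  set.seed(1)
  x <- raw_eeg(matrix(rnorm(2 * 10), nrow = 2), fs = 256,
               channel_names = c("Fp1", "Fp2"), trial_id = "t7")
  f <- withr::local_tempfile(fileext = ".txt")
  write_recording(x, f)
  y <- read_recording(f)
  expect_identical(y$data, x$data)
  expect_equal(y$fs, 256)
  expect_equal(y$channel_names, c("Fp1", "Fp2"))
  expect_equal(y$trial_id, "t7")
})

test_that("matrix reader rejects files without rate metadata or with NaN", {
  f <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("1 2 3", "4 5 6"), f)
  expect_error(read_recording(f), "sampling-rate header")

  f2 <- withr::local_tempfile(fileext = ".txt")
  writeLines(c("# fs=128 channels=a,b", "1 2 NaN", "4 5 6"), f2)
  expect_error(read_recording(f2), "sample index")

  expect_error(read_recording(file.path(tempdir(), "no_such_file.txt")),
               "does not exist")
})

test_that("EDF round-trip agrees within 16-bit quantization", {
  set.seed(2)
  x <- raw_eeg(matrix(rnorm(3 * 512, sd = 40), nrow = 3), fs = 256,
               trial_id = "edf1")
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(x, f)
  y <- read_recording(f)
  expect_equal(y$fs, 256)
  expect_equal(y$channel_names, x$channel_names)
  quant <- max(apply(x$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(y$data - x$data)), 1.5 * quant)
})

test_that("EDF writer splits long recordings into records transparently", {
  set.seed(3)
  # 8 ch x 12288 samples would exceed one EDF record; forces multi-record
  x <- raw_eeg(matrix(rnorm(8 * 12288), nrow = 8), fs = 1024)
  f <- withr::local_tempfile(fileext = ".edf")
  write_recording(x, f)
  y <- read_recording(f)
  expect_equal(dim(y$data), dim(x$data))
  expect_equal(y$fs, x$fs)
  quant <- max(apply(x$data, 1, function(v) diff(range(v)))) / 65535
  expect_lt(max(abs(y$data - x$data)), 1.5 * quant)
})

test_that("rating binarization respects inclusive boundaries and excludes the middle", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,valence,arousal",
               "t1,2,8", "t2,5,5", "t3,7,3", "t4,3,7", "t5,1,9"), f)
  lab <- read_labels(f)
  expect_equal(as.character(lab$class_valence),
               c("negative", "excluded", "positive", "negative", "negative"))
  expect_equal(as.character(lab$class_arousal),
               c("active", "excluded", "passive", "active", "active"))
  # partition: every label in exactly one bin
  expect_false(any(is.na(lab$class_valence)))
  expect_setequal(levels(lab$class_valence),
                  c("negative", "positive", "excluded"))
})

test_that("label reading rejects bad scores, duplicates and missing columns", {
  f <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,valence,arousal", "t1,10,5"), f)
  expect_error(read_labels(f), "\\[1, 9\\]")

  f2 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,valence,arousal", "t1,5,5", "t1,6,6"), f2)
  expect_error(read_labels(f2), "duplicate")

  f3 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("trial_id,valence", "t1,5"), f3)
  expect_error(read_labels(f3), "arousal")
})

test_that("downsampling halves, preserves tones and refuses upsampling", {
  t512 <- (0:511) / 512
  x <- raw_eeg(matrix(sin(2 * pi * 10 * t512), nrow = 1), fs = 512)
  y <- downsample(x, 256)
  expect_equal(y$fs, 256)
  expect_equal(ncol(y$data), 256)
  ref <- sin(2 * pi * 10 * (0:255) / 256)
  expect_gt(cor(as.numeric(y$data), ref), 0.99)

  expect_identical(downsample(x, 512), x)  # pass-through
  expect_error(downsample(x, 1024), "upsampling")
  expect_error(downsample(x, -1), "positive")
})

test_that("downsampling handles rational ratios and attenuates aliases >= 40 dB", {
  t300 <- (0:899) / 300
  x <- raw_eeg(matrix(sin(2 * pi * 10 * t300), nrow = 1), fs = 300)
  y <- downsample(x, 256)
  expect_equal(ncol(y$data), round(900 * 256 / 300))
  expect_gt(cor(as.numeric(y$data),
                sin(2 * pi * 10 * (0:(ncol(y$data) - 1)) / 256)), 0.99)
  # duration preserved within one sample period
  expect_lt(abs(ncol(y$data) / y$fs - 900 / 300), 1 / 256)

  t512 <- (0:511) / 512
  hi <- raw_eeg(matrix(sin(2 * pi * 200 * t512), nrow = 1), fs = 512)
  z <- downsample(hi, 256)  # 200 Hz sits above the new Nyquist
  att_db <- 10 * log10(var(as.numeric(z$data)) / 0.5)
  expect_lt(att_db, -40)
})

test_that("the preprocessing hook defaults to pass-through", {
  x <- raw_eeg(matrix(rnorm(20), nrow = 2), fs = 10)
  expect_identical(preprocess_hook(x), x)
  y <- preprocess_hook(x, function(r) {
    r$data <- r$data - rowMeans(r$data)
    r
  })
  expect_equal(rowMeans(y$data), c(CH1 = 0, CH2 = 0), tolerance = 1e-12)
  expect_error(preprocess_hook(x, function(r) r$data), "raw_eeg")
})

test_that("the dataset-directory adapter loads a documented layout and fails clearly", {
  expect_error(load_deap_trial_set(file.path(tempdir(), "nope")),
               "optional")
  dir <- withr::local_tempdir()
  expect_error(load_deap_trial_set(dir), "labels.csv")

  # synthetic mini-dataset in the documented layout
  set.seed(9)
  ids <- sprintf("s01_t%02d", 1:6)
  scores_v <- c(2, 8, 5, 3, 7, 9)
  scores_a <- c(8, 2, 5, 7, 3, 1)
  writeLines(c("trial_id,valence,arousal",
               sprintf("%s,%d,%d", ids, scores_v, scores_a)),
             file.path(dir, "labels.csv"))
  for (id in ids)
    write_recording(raw_eeg(matrix(rnorm(2 * 64), nrow = 2), fs = 128,
                            trial_id = id),
                    file.path(dir, paste0(id, ".txt")))
  ds <- load_deap_trial_set(dir)
  expect_length(ds$trials, 6)
  expect_equal(ds$trials[[1]]$fs, 128)  # rate read from file, not assumed
  expect_equal(sum(ds$labels$class_valence == "negative"), 2)
  expect_equal(sum(ds$labels$class_valence == "positive"), 3)
  expect_equal(sum(ds$labels$class_arousal == "passive"), 3)
})
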