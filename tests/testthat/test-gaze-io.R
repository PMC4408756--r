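make_samples <- function(time_ms, x = 0.25, y = 0.5, vl = 0L, vr = 0L,
                         participant = "P01", conversation = "C1") {
  n <- length(time_ms)
  data.frame(
    participant_id = participant, group = "TODDLER",
    conversation_id = conversation, trial_index = 1L,
    time_ms = time_ms,
    validity_left = rep_len(vl, n), validity_right = rep_len(vr, n),
    x = rep_len(x, n), y = rep_len(y, n),
    stringsAsFactors = FALSE
  )
}

test_that("gaze tables round-trip through CSV and TSV", {
  s <- make_samples(seq(0L, 980L, 20L))
  for (ext in c(".csv", ".tsv")) {
    path <- withr::local_tempfile(fileext = ext)
    write_gaze_table(s, path)
    r <- read_gaze_table(path)
    expect_equal(r$time_ms, s$time_ms)
    expect_equal(r$x, s$x)
  }
})

test_that("nominal sampling rate is inferred from the median interval", {
  t50 <- seq(0L, 29980L, 20L)
  expect_equal(infer_sampling_rate(t50), 50)
  t120 <- as.integer(round((0:3599) * 1000 / 120))
  expect_equal(infer_sampling_rate(t120), 120)

  # a 30 s, 50 Hz trial yields ~1500 samples with rate 50
  s <- make_samples(t50)
  rec <- trial_recordings(s)
  expect_length(rec, 1L)
  expect_equal(rec[[1]]$nominal_rate_hz, 50)
  expect_equal(nrow(rec[[1]]$samples), 1500L)
})

test_that("duplicated or non-monotone timestamps raise errors naming the row", {
  s <- make_samples(c(0L, 20L, 20L, 40L))
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(s, path)
  expect_error(read_gaze_table(path), "duplicated timestamp at row 3")

  s2 <- make_samples(c(0L, 40L, 20L, 60L))
  write_gaze_table(s2, path)
  expect_error(read_gaze_table(path), "non-monotone timestamp at row 3")
})

test_that("missing required columns are reported by name", {
  s <- make_samples(seq(0L, 100L, 20L))
  s$validity_right <- NULL
  path <- withr::local_tempfile(fileext = ".csv")
  utils::write.csv(s, path, row.names = FALSE)
  expect_error(read_gaze_table(path), "validity_right")
})

test_that("a sample is valid when at least one eye is valid", {
  expect_true(is_valid_sample(0L, 4L))   # left eye only
  expect_true(is_valid_sample(4L, 1L))   # right eye only
  expect_true(is_valid_sample(0L, 0L))   # both
  expect_false(is_valid_sample(4L, 4L))  # neither
  expect_equal(is_valid_sample(c(0L, 4L), c(4L, 4L)), c(TRUE, FALSE))
})

test_that("resolve_aoi is total over the four labels", {
  lay <- default_aoi_layout()
  expect_equal(resolve_aoi(0.25, 0.5, TRUE, lay), "LEFT")
  expect_equal(resolve_aoi(0.75, 0.5, TRUE, lay), "RIGHT")
  expect_equal(resolve_aoi(0.5, 0.5, TRUE, lay), "OTHER")    # between puppets
  expect_equal(resolve_aoi(0.25, 0.5, FALSE, lay), "OFFSCREEN") # invalid
  expect_equal(resolve_aoi(NA, NA, TRUE, lay), "OFFSCREEN")  # missing coords
  expect_equal(resolve_aoi(1.2, 0.5, TRUE, lay), "OFFSCREEN") # off screen
  # boundary points belong to the region (closed rectangles)
  expect_equal(resolve_aoi(lay$left[2], 0.5, TRUE, lay), "LEFT")
  expect_equal(resolve_aoi(lay$right[1], 0.5, TRUE, lay), "RIGHT")
})

test_that("AOI layouts must be disjoint and inside the screen", {
  expect_error(aoi_layout(left = c(0, 0.6, 0, 1), right = c(0.5, 1, 0, 1)),
               "disjoint")
  expect_error(aoi_layout(left = c(-0.1, 0.4, 0, 1)), "inside the screen")
  path <- withr::local_tempfile(fileext = ".yaml")
  write_aoi_layout(default_aoi_layout(), path)
  expect_equal(read_aoi_layout(path), default_aoi_layout())
})

test_that("the pre-resolved AOI dialect passes labels through", {
  s <- make_samples(seq(0L, 100L, 20L))
  s$x <- NULL; s$y <- NULL
  s$aoi <- c("LEFT", "LEFT", "RIGHT", "OTHER", "OFFSCREEN", "LEFT")
  path <- withr::local_tempfile(fileext = ".csv")
  write_gaze_table(s, path)
  r <- read_gaze_table(path, dialect = "aoi")
  expect_identical(resolve_sample_aois(r)$aoi, s$aoi)
})
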