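test_that("segmentation produces maximal dwell runs and bridges short gaps", {
  # constant LEFT for 200 ms at 50 Hz
  t <- seq(0L, 180L, 20L)
  fx <- segment_fixations(t, rep("LEFT", 10))
  expect_equal(nrow(fx), 1L)
  expect_equal(fx$offset_ms - fx$onset_ms, 200)

  # LEFT 80 ms, OFFSCREEN 20 ms, LEFT 80 ms; tolerance 25 ms merges to 180 ms
  t2 <- seq(0L, 160L, 20L)
  aoi2 <- c(rep("LEFT", 4), "OFFSCREEN", rep("LEFT", 4))
  merged <- segment_fixations(t2, aoi2, gap_tolerance_ms = 25)
  expect_equal(nrow(merged), 1L)
  expect_equal(merged$aoi, "LEFT")
  expect_equal(merged$offset_ms - merged$onset_ms, 180)

  # with zero tolerance the same stream keeps three runs
  strict <- segment_fixations(t2, aoi2, gap_tolerance_ms = 0)
  expect_equal(strict$aoi, c("LEFT", "OFFSCREEN", "LEFT"))
  expect_equal(strict$offset_ms - strict$onset_ms, c(80, 20, 80))

  # strict per-sample alternation at 50 Hz: no dwell reaches 100 ms
  t3 <- seq(0L, 980L, 20L)
  aoi3 <- rep(c("LEFT", "RIGHT"), 25)
  alt <- segment_fixations(t3, aoi3, gap_tolerance_ms = 0)
  expect_true(max(alt$offset_ms - alt$onset_ms) < 100)

  # consecutive fixations always have distinct AOIs
  expect_true(all(alt$aoi[-1] != alt$aoi[-nrow(alt)]))
})

test_that("analysis windows are centered on the silence with group-specific leads", {
  w_t <- build_analysis_window(10000, 10500, "LEFT", "RIGHT", "TODDLER", 30000)
  expect_equal(w_t$start_ms, 9700)
  expect_equal(w_t$end_ms, 10800)
  expect_equal(w_t$deadline_ms, 10800)
  expect_equal(w_t$response_onset_ms, 10500)

  w_a <- build_analysis_window(10000, 10500, "LEFT", "RIGHT", "ADULT", 30000)
  expect_equal(w_a$start_ms, 9800)
  expect_equal(w_a$end_ms, 10700)
  expect_equal(w_a$deadline_ms, 10700)

  # clipping at the conversation start
  w_c <- build_analysis_window(100, 600, "LEFT", "RIGHT", "TODDLER", 30000)
  expect_equal(w_c$start_ms, 0)
  expect_equal(w_c$deadline_ms, 900)
})

fix_df <- function(...) {
  rows <- list(...)
  data.frame(
    aoi = vapply(rows, `[[`, "", 1),
    onset_ms = as.numeric(vapply(rows, `[[`, "", 2)),
    offset_ms = as.numeric(vapply(rows, `[[`, "", 3)),
    stringsAsFactors = FALSE
  )
}

test_that("the detector applies the three-criterion checklist", {
  w <- build_analysis_window(10000, 10500, "LEFT", "RIGHT", "TODDLER", 30000)

  # prior-speaker fixation then a timely responder fixation
  hit <- fix_df(c("LEFT", "9500", "10100"), c("RIGHT", "10200", "10400"))
  expect_equal(detect_anticipatory_switch(hit, w), 1L)
  det <- detect_anticipatory_switch(hit, w, details = TRUE)
  expect_equal(det$initiation_ms, 10200)

  # identical but initiated after the 300 ms deadline
  late <- fix_df(c("LEFT", "9500", "10100"), c("RIGHT", "10850", "11050"))
  expect_equal(detect_anticipatory_switch(late, w), 0L)

  # gaze on the prior speaker the whole window, never on the responder
  stare <- fix_df(c("LEFT", "9000", "12000"))
  expect_equal(detect_anticipatory_switch(stare, w), 0L)

  # responder fixation without a preceding prior-speaker fixation
  no_f1 <- fix_df(c("OTHER", "9000", "10100"), c("RIGHT", "10200", "10400"))
  expect_equal(detect_anticipatory_switch(no_f1, w), 0L)

  # sub-100 ms dwells never qualify
  short <- fix_df(c("LEFT", "9950", "10040"), c("RIGHT", "10100", "10400"))
  expect_equal(detect_anticipatory_switch(short, w), 0L)
})

test_that("the detector matches the brute-force pair enumeration", {
  set.seed(401)
  for (case in 1:400) {
    fx <- random_fixations(sample(1:12, 1))
    w <- random_window()
    strict <- sample(c(TRUE, FALSE), 1)
    expect_identical(
      detect_anticipatory_switch(fx, w, strict_prior = strict),
      brute_force_detect(fx, w, strict_prior = strict)
    )
  }
})

test_that("shrinking the window or raising the dwell criterion never creates a switch", {
  set.seed(402)
  for (case in 1:200) {
    fx <- random_fixations(sample(2:12, 1))
    w <- random_window()
    base <- detect_anticipatory_switch(fx, w)

    harder <- detect_anticipatory_switch(fx, w, min_fix_ms = 150)
    expect_lte(harder, base)

    w_shrunk <- w
    w_shrunk$start_ms <- w$start_ms + 100
    w_shrunk$deadline_ms <- w$deadline_ms - 100
    shrunk <- detect_anticipatory_switch(fx, w_shrunk)
    expect_lte(shrunk, base)
  }
})

test_that("the same gaze trajectory gives the same result at 50 and 120 Hz", {
  # continuous AOI timeline with boundaries well clear of criterion edges
  timeline <- fix_df(
    c("LEFT", "0", "10140"),
    c("RIGHT", "10140", "10640"),
    c("OTHER", "10640", "30000")
  )
  aoi_at <- function(t) {
    timeline$aoi[findInterval(t, timeline$onset_ms)]
  }
  w <- build_analysis_window(10000, 10500, "LEFT", "RIGHT", "TODDLER", 30000)
  res <- vapply(c(50, 120), function(rate) {
    t <- as.integer(round((0:(30 * rate - 1)) * 1000 / rate))
    fx <- segment_fixations(t, aoi_at(t))
    detect_anticipatory_switch(fx, w)
  }, 0L)
  expect_equal(res[1], res[2])
  expect_equal(res[1], 1L)
})
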