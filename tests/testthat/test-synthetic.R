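noise_free <- function(group, ...) {
  sim_params(group, dropout_rate = 0, lapse_rate_hz = 0, ...)
}

test_that("cohort simulation is deterministic and has the right shape", {
  spec <- cohort_spec(n_toddlers = 2, n_adults = 2, seed = 13)
  a <- simulate_cohort(spec)
  b <- simulate_cohort(spec)
  expect_identical(a, b)
  expect_equal(length(trial_recordings(a$samples)), 4 * 8)
  expect_equal(nrow(a$truth), 4 * 32)
  # presentation orders alternate between the two experiment versions
  rec <- trial_recordings(a$samples)
  conv_order <- function(pid) {
    vapply(Filter(function(r) r$participant_id == pid, rec),
           `[[`, "", "conversation_id")
  }
  expect_false(identical(conv_order("T01"), conv_order("T02")))
})

test_that("the study-sized cohort yields 37 x 8 recordings", {
  spec <- cohort_spec(seed = 29) # defaults: 21 toddlers, 16 adults
  sim <- simulate_cohort(spec)
  expect_equal(length(trial_recordings(sim$samples)), 37 * 8)
  expect_equal(nrow(sim$truth), 37 * 32)
})

trial_detections <- function(sim, gap_tolerance_ms = 75) {
  recs <- trial_recordings(resolve_sample_aois(sim$samples))
  conv_ids <- vapply(sim$design$conversations, `[[`, "", "id")
  do.call(rbind, lapply(recs, function(rec) {
    cv <- sim$design$conversations[[match(rec$conversation_id, conv_ids)]]
    fx <- segment_fixations(rec$samples$time_ms, rec$samples$aoi,
                            gap_tolerance_ms)
    w <- analysis_windows(cv, rec$group)
    data.frame(participant_id = rec$participant_id,
               conversation_id = rec$conversation_id,
               item_id = w$item_id, condition = w$condition,
               detected = detect_windows(fx, w), stringsAsFactors = FALSE)
  }))
}

test_that("with zero noise the detector reproduces the ground-truth labels", {
  spec <- cohort_spec(n_toddlers = 3, n_adults = 3, seed = 41,
                      params_toddler = noise_free("TODDLER"),
                      params_adult = noise_free("ADULT"))
  sim <- simulate_cohort(spec)
  det <- trial_detections(sim)
  m <- merge(det, sim$truth, by = c("participant_id", "conversation_id",
                                    "item_id", "condition"))
  expect_equal(nrow(m), nrow(sim$truth))
  expect_identical(m$detected, m$truth)
  expect_true(any(m$truth == 1) && any(m$truth == 0))
})

test_that("certain anticipation with fixed latency is always detected", {
  certain <- function(group) {
    noise_free(group,
               switch_prob = c(FULLY_INCOMPLETE = 1, INCOMPLETE_SYNTAX = 1,
                               INCOMPLETE_PROSODY = 1, FULLY_COMPLETE = 1),
               switch_latency_sd = 0)
  }
  spec <- cohort_spec(n_toddlers = 2, n_adults = 2, seed = 43,
                      params_toddler = certain("TODDLER"),
                      params_adult = certain("ADULT"))
  sim <- simulate_cohort(spec)
  det <- trial_detections(sim)
  expect_true(all(det$detected == 1L))
})

test_that("a zero-anticipation speaker-follower never trips the detector", {
  never <- function(group) {
    noise_free(group,
               switch_prob = c(FULLY_INCOMPLETE = 0, INCOMPLETE_SYNTAX = 0,
                               INCOMPLETE_PROSODY = 0, FULLY_COMPLETE = 0))
  }
  spec <- cohort_spec(n_toddlers = 2, n_adults = 2, seed = 47,
                      params_toddler = never("TODDLER"),
                      params_adult = never("ADULT"))
  sim <- simulate_cohort(spec)
  det <- trial_detections(sim)
  expect_true(all(det$detected == 0L))
  expect_true(all(sim$truth$truth == 0L))
})

test_that("total dropout empties the trial upstream", {
  spec <- cohort_spec(n_toddlers = 1, n_adults = 0, seed = 53,
                      params_toddler = sim_params("TODDLER", dropout_rate = 1))
  sim <- simulate_cohort(spec)
  att <- attention_table(sim$samples)
  expect_true(all(att$on_screen_fraction == 0))
  pre <- preprocess_samples(sim$samples)
  expect_equal(nrow(pre$kept), 0L)
  expect_true(all(pre$audit$participant_excluded))
})

test_that("detected switch rates preserve the condition probability ordering", {
  spec <- cohort_spec(n_toddlers = 8, n_adults = 8, seed = 59)
  sim <- simulate_cohort(spec)
  det <- trial_detections(sim)
  rates <- tapply(det$detected, det$condition, mean)
  expect_true(rates[["FULLY_COMPLETE"]] > rates[["INCOMPLETE_PROSODY"]])
  expect_true(rates[["INCOMPLETE_PROSODY"]] > rates[["INCOMPLETE_SYNTAX"]])
  expect_true(rates[["INCOMPLETE_SYNTAX"]] > rates[["FULLY_INCOMPLETE"]])
})
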