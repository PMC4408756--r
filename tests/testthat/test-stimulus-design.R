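test_that("generated designs satisfy every structural constraint", {
  for (seed in 1:4) {
    d <- generate_design(seed)
    expect_identical(validate_design(d), character(0))

    tg <- design_targets(d)
    expect_equal(nrow(tg), 32L)
    expect_true(all(table(tg$condition) == 8L))
    expect_true(all(table(tg$prior_speaker) == 16L))
    expect_true(all(table(tg$condition, tg$prior_speaker) == 4L))

    flags <- condition_flags(tg$condition)
    expect_true(all(tg$outcome[!flags$syntax_complete] == "CONTINUE"))
    for (lab in c("INCOMPLETE_PROSODY", "FULLY_COMPLETE")) {
      expect_equal(sum(tg$condition == lab & tg$outcome == "SWITCH"), 4L)
    }

    for (cv in d$conversations) {
      ut <- cv$utterances
      expect_equal(nrow(ut), 10L)
      expect_equal(sum(ut$is_target), 4L)
      expect_true(all(ut$onset_ms[-1] - ut$offset_ms[-10] == 500L))
      expect_true(cv$n_transitions >= 5L && cv$n_transitions <= 7L)
      expect_true(cv$duration_ms >= 29000L && cv$duration_ms <= 31000L)
      expect_true(all(cv$targets$silence_offset_ms -
                        cv$targets$silence_onset_ms == 500L))
    }
  }
})

test_that("design generation is deterministic in the seed and varies across seeds", {
  expect_identical(generate_design(3), generate_design(3))
  a <- generate_design(0)
  b <- generate_design(1)
  expect_identical(validate_design(a), character(0))
  expect_identical(validate_design(b), character(0))
  # target ordering or timings differ between seeds
  expect_false(identical(a$conversations, b$conversations))
})

test_that("validate_design names the violated constraint and its location", {
  d <- generate_design(5)

  d1 <- d
  idx <- which(d1$conversations[[1]]$targets$condition == "FULLY_INCOMPLETE")
  d1$conversations[[1]]$targets$outcome[idx] <- "SWITCH"
  v1 <- validate_design(d1)
  expect_true(any(grepl("continuation", v1)))

  d2 <- d
  d2$conversations[[2]]$targets <- d2$conversations[[2]]$targets[1:3, ]
  v2 <- validate_design(d2)
  expect_true(any(grepl("expected 4 target events", v2)))

  d3 <- d
  d3$conversations[[3]]$targets$silence_offset_ms[1] <-
    d3$conversations[[3]]$targets$silence_onset_ms[1] + 400L
  v3 <- validate_design(d3)
  expect_true(any(grepl("500 ms", v3)))
})

test_that("designs round-trip exactly through the YAML design format", {
  d <- generate_design(7)
  path <- withr::local_tempfile(fileext = ".yaml")
  save_design(d, path)
  expect_identical(load_design(path), d)
})

test_that("loading a malformed or constraint-breaking design file errors", {
  path <- withr::local_tempfile(fileext = ".yaml")

  writeLines("format: something-else", path)
  expect_error(load_design(path), "not a turngaze design")

  d <- generate_design(9)
  # overlapping utterances: first utterance runs past the next one's onset
  d_bad <- d
  d_bad$conversations[[1]]$utterances$offset_ms[1] <-
    d_bad$conversations[[1]]$utterances$onset_ms[2] + 100L
  save_design(d_bad, path)
  expect_error(load_design(path), "separated by exactly 500 ms")

  # 400 ms target silence
  d_bad2 <- d
  d_bad2$conversations[[1]]$targets$silence_offset_ms[2] <-
    d_bad2$conversations[[1]]$targets$silence_onset_ms[2] + 400L
  save_design(d_bad2, path)
  expect_error(load_design(path), "500 ms")
})

test_that("condition labels biject with the completeness flags", {
  tab <- condition_table()
  expect_identical(condition_label(tab$syntax_complete, tab$prosody_complete),
                   tab$label)
  fl <- condition_flags(tab$label)
  expect_identical(fl$syntax_complete, tab$syntax_complete)
  expect_identical(fl$prosody_complete, tab$prosody_complete)
  expect_error(condition_flags("HALF_COMPLETE"), "unknown condition")
})
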