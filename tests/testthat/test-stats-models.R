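# A small shared cohort for the model-structure tests (computed once).
local_obs <- local({
  spec <- cohort_spec(n_toddlers = 5, n_adults = 5, seed = 77)
  sim <- simulate_cohort(spec)
  pre <- preprocess_samples(sim$samples)
  compute_switch_observations(pre$kept, sim$design, n_shuffles = 30, seed = 9)
})

test_that("contrast coding maps levels exactly as in the model tables", {
  expect_equal(code_contrasts(c("incomplete", "complete"), "syntax"), c(-1, 1))
  expect_equal(code_contrasts("complete", "prosody"), 1)
  expect_equal(code_contrasts(c("toddler", "adult", "TODDLER"), "group"),
               c(-1, 1, -1))
  expect_equal(code_contrasts(c("no", "yes"), "speaker_change"), c(-1, 1))
  expect_equal(code_contrasts(c("CONTINUE", "SWITCH"), "speaker_change"),
               c(-1, 1))
  expect_equal(
    code_contrasts(c("INCOMPLETE_SYNTAX", "INCOMPLETE_PROSODY"),
                   "partial_condition"),
    c(-1, 1))
  expect_error(code_contrasts("kind_of_complete", "syntax"), "unknown level")
})

test_that("a constant response yields zero fixed effects, flagged not crashed", {
  obs <- local_obs
  obs$corrected <- 0
  fit <- fit_mixed_model(obs, "syn_code * pros_code * group_code")
  expect_true(all(abs(fit$coefficients$beta) < 1e-8))
  expect_true(fit$singular)
  expect_false(any(fit$coefficients$significant))
})

test_that("fits report crossed subject and item intercepts plus a residual", {
  fit <- fit_mixed_model(local_obs, "syn_code * pros_code * group_code")
  expect_setequal(fit$varcomp$component,
                  c("participant_id", "item_id", "Residual"))
  expect_equal(nrow(fit$varcomp), 3L)
  expect_equal(fit$n_obs, nrow(local_obs))
  expect_equal(fit$n_subjects, length(unique(local_obs$participant_id)))
  expect_equal(fit$coefficients$z,
               fit$coefficients$beta / fit$coefficients$se)
})

test_that("swapping a factor's codes flips signs but not |z|", {
  obs <- local_obs
  f1 <- fit_mixed_model(obs, "syn_code * pros_code")
  obs$syn_code <- -obs$syn_code
  f2 <- fit_mixed_model(obs, "syn_code * pros_code")
  expect_equal(abs(f1$coefficients$z), abs(f2$coefficients$z),
               tolerance = 1e-6)
  i <- match("syn_code", f1$coefficients$term)
  expect_equal(f1$coefficients$beta[i], -f2$coefficients$beta[i],
               tolerance = 1e-8)
})

test_that("the suite fits the six models with the expected structure", {
  suite <- run_model_suite(local_obs)
  expect_named(suite, c("main", "partial_conditions", "complete_syntax",
                        "speaker_change", "first_two_trials",
                        "last_two_trials"))
  n_terms <- vapply(suite, function(f) nrow(f$coefficients), 0L)
  expect_equal(unname(n_terms), c(8L, 4L, 4L, 8L, 8L, 8L))

  # the partial model uses only the two partially complete conditions
  expect_equal(suite$partial_conditions$n_obs,
               sum(local_obs$condition %in%
                     c("INCOMPLETE_SYNTAX", "INCOMPLETE_PROSODY")))
  # the speaker-change model contains no syntactically incomplete items
  expect_equal(suite$speaker_change$n_obs, sum(local_obs$syn_code == 1))
  # first/last two trials are presentation positions {1,2} and {7,8}
  expect_equal(suite$first_two_trials$n_obs,
               sum(local_obs$presentation_index <= 2))
  expect_equal(suite$last_two_trials$n_obs,
               sum(local_obs$presentation_index >= 7))
})

test_that("item exclusion and empty subsets are handled explicitly", {
  drop <- unique(local_obs$item_id)[1:2]
  suite <- run_model_suite(local_obs, exclude_items = drop)
  expect_equal(suite$main$n_obs,
               sum(!local_obs$item_id %in% drop))

  late_only <- local_obs[local_obs$presentation_index >= 5, ]
  expect_error(run_model_suite(late_only), "first-two-trials")
})

test_that("condition summaries report participant-level means and SEMs", {
  # four participants with corrected values 0, 0, 1, 1 in one cell
  obs <- expand.grid(participant_id = paste0("P", 1:4),
                     condition = condition_table()$label,
                     stringsAsFactors = FALSE)
  obs$group <- "TODDLER"
  obs$item_id <- paste0("I_", obs$condition)
  obs$actual <- ifelse(obs$participant_id %in% c("P3", "P4"), 1, 0)
  obs$baseline <- 0.25
  obs$corrected <- obs$actual - obs$baseline

  s <- condition_summary(obs)
  expect_equal(nrow(s), 4L) # one group present: 4 condition rows
  expect_equal(s$actual_mean, rep(0.5, 4))
  expect_equal(s$actual_sem, rep(sd(c(0, 0, 1, 1)) / 2, 4))
  expect_equal(s$baseline_sem, rep(0, 4))
  expect_equal(s$corrected_mean, rep(0.25, 4))

  # with both groups the summary has one row per condition x group
  s2 <- condition_summary(local_obs)
  expect_equal(nrow(s2), 8L)
  expect_setequal(unique(s2$group), c("TODDLER", "ADULT"))
})
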