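# Synthetic gaze cohorts. The generator emulates a participant watching the
# dyadic puppet videos: a background gaze process (speaker-following with a
# reaction latency, or a side-symmetric alternation for null calibration),
# per-condition probabilities of planning an anticipatory switch to the
# responder during a target silence, group-specific saccade-planning
# latencies, attention lapses and tracker validity dropout. Every gaze event
# is snapped to the sample grid, and each target carries a ground-truth
# anticipation label computed from the noise-free gaze timeline, so detector
# output can be checked against the generator in closed loop.

#' Simulation parameters for one participant group
#'
#' Defaults emulate the study conditions: 50 Hz sampling, a 500 ms silence at
#' every target, toddlers needing at least 300 ms to plan a gaze shift
#' (`switch_latency_floor_ms`), reactive (speaker-following) shifts slower
#' than the group anticipation deadline, occasional attention lapses and more
#' tracker dropout for toddlers than adults. The per-condition anticipatory
#' switch probabilities are ordered fully complete > incomplete prosody >
#' incomplete syntax > fully incomplete, mirroring the graded availability of
#' completion cues.
#'
#' @param group `"TODDLER"` or `"ADULT"`; sets the latency, dropout and rate
#'   defaults.
#' @param switch_prob named probability per condition of planning an
#'   anticipatory switch at a target.
#' @param background `"speaker_following"` (gaze tracks the current speaker)
#'   or `"symmetric"` (side-symmetric random alternation, for null
#'   calibration).
#' @param follow_latency_mean,follow_latency_sd,follow_latency_floor_ms
#'   reactive gaze-shift latency after an utterance onset (ms).
#' @param switch_latency_mean,switch_latency_sd,switch_latency_floor_ms
#'   anticipatory shift latency after a target silence onset (ms); draws
#'   exceeding the detection deadline are kept and become intended-but-late
#'   switches scored 0.
#' @param mean_dwell_ms mean dwell per side for the symmetric background.
#' @param lapse_rate_hz attention-lapse episodes per second.
#' @param lapse_mean_ms mean lapse duration.
#' @param lapse_p_offscreen probability a lapse goes off screen rather than
#'   to a non-speaker screen region.
#' @param dropout_rate per-sample probability the tracker loses both eyes.
#' @param sampling_rate_hz tracker rate (50 or 120 in the emulated setups).
#' @return A list of class `sim_params`.
#' @export
sim_params <- function(group = c("TODDLER", "ADULT"),
                       switch_prob = c(FULLY_INCOMPLETE = 0.10,
                                       INCOMPLETE_SYNTAX = 0.25,
                                       INCOMPLETE_PROSODY = 0.50,
                                       FULLY_COMPLETE = 0.70),
                       background = c("speaker_following", "symmetric"),
                       follow_latency_mean = NULL,
                       follow_latency_sd = NULL,
                       follow_latency_floor_ms = NULL,
                       switch_latency_mean = NULL,
                       switch_latency_sd = NULL,
                       switch_latency_floor_ms = NULL,
                       mean_dwell_ms = 1000,
                       lapse_rate_hz = 0.03,
                       lapse_mean_ms = 800,
                       lapse_p_offscreen = 0.5,
                       dropout_rate = NULL,
                       sampling_rate_hz = NULL) {
  group <- match.arg(group)
  background <- match.arg(background)
  toddler <- group == "TODDLER"
  p <- list(
    group = group,
    switch_prob = switch_prob,
    background = background,
    follow_latency_mean = follow_latency_mean %||% (if (toddler) 500 else 400),
    follow_latency_sd = follow_latency_sd %||% (if (toddler) 150 else 100),
    follow_latency_floor_ms = follow_latency_floor_ms %||% (if (toddler) 350 else 250),
    switch_latency_mean = switch_latency_mean %||% (if (toddler) 500 else 350),
    switch_latency_sd = switch_latency_sd %||% (if (toddler) 150 else 100),
    switch_latency_floor_ms = switch_latency_floor_ms %||% (if (toddler) 300 else 150),
    mean_dwell_ms = mean_dwell_ms,
    lapse_rate_hz = lapse_rate_hz,
    lapse_mean_ms = lapse_mean_ms,
    lapse_p_offscreen = lapse_p_offscreen,
    dropout_rate = dropout_rate %||% (if (toddler) 0.05 else 0.01),
    sampling_rate_hz = sampling_rate_hz %||% 50
  )
  check_that(setequal(names(p$switch_prob), CONDITION_LEVELS),
             "switch_prob must name all four conditions")
  check_that(all(p$switch_prob >= 0 & p$switch_prob <= 1),
             "switch probabilities must lie in [0, 1]")
  check_that(p$mean_dwell_ms > 0, "mean dwell must be positive")
  check_that(p$dropout_rate >= 0 && p$dropout_rate <= 1,
             "dropout rate must lie in [0, 1]")
  check_that(p$sampling_rate_hz > 0, "sampling rate must be positive")
  structure(p, class = "sim_params")
}

# coordinate emission per AOI label; jitter is clipped inside the region so
# labels survive the round trip through resolve_aoi()
aoi_to_xy <- function(aoi, layout = default_aoi_layout()) {
  n <- length(aoi)
  x <- rep(NA_real_, n)
  y <- rep(NA_real_, n)
  jit <- function(center, sd, lo, hi) {
    pmin(hi, pmax(lo, center + stats::rnorm(sum(idx), 0, sd)))
  }
  for (lab in c("LEFT", "RIGHT")) {
    r <- layout[[tolower(lab)]]
    idx <- aoi == lab
    if (!any(idx)) next
    x[idx] <- jit((r[1] + r[2]) / 2, 0.03, r[1], r[2])
    y[idx] <- jit((r[3] + r[4]) / 2, 0.03, r[3], r[4])
  }
  idx <- aoi == "OTHER"
  if (any(idx)) {
    # the inter-puppet gap: on screen, in neither region
    lo <- layout$left[2] + 1e-3
    hi <- layout$right[1] - 1e-3
    x[idx] <- jit((lo + hi) / 2, 0.005, lo, hi)
    y[idx] <- jit(0.5, 0.1, layout$screen[3], layout$screen[4])
  }
  list(x = x, y = y)
}

#' Simulate one gaze trial over a conversation
#'
#' Builds a gaze-event timeline (background process plus, at each target,
#' a responder-directed shift planned with the condition's probability and a
#' group-specific latency from the silence onset), snaps events to the sample
#' grid, overlays attention lapses and validity dropout, and emits samples in
#' the gaze-table schema. Ground-truth labels are the detector criteria
#' evaluated on the noise-free event timeline: an intended switch that is
#' initiated after the deadline, or whose surrounding dwells are too short,
#' is labelled 0.
#'
#' @param conversation one conversation from an `experiment_design`.
#' @param params a [sim_params()] object.
#' @param participant_id,trial_index identifiers stamped on the samples.
#' @param leads group anticipation leads, see [group_lead_ms()].
#' @param min_fix_ms,gap_tolerance_ms detector settings used for the
#'   ground-truth evaluation.
#' @param layout AOI layout used to emit coordinates.
#' @return A list with `samples` (gaze table rows) and `truth` (one row per
#'   target: `item_id`, `condition`, `outcome`, `intended`, `truth`).
#' @export
sample_gaze_trial <- function(conversation, params,
                              participant_id = "P01", trial_index = 1L,
                              leads = GROUP_LEADS_MS, min_fix_ms = 100,
                              gap_tolerance_ms = 75,
                              layout = default_aoi_layout()) {
  dur <- conversation$duration_ms
  rate <- params$sampling_rate_hz
  n <- floor(dur * rate / 1000)
  times <- as.integer(round((seq_len(n) - 1L) * 1000 / rate))
  snap_up <- function(t) {
    # smallest sample time >= t (capped at the last sample)
    i <- findInterval(t, times)
    hit <- i >= 1L & abs(times[pmax(i, 1L)] - t) < 1e-9
    j <- ifelse(hit, i, i + 1L)
    times[pmax(1L, pmin(n, j))]
  }
  rnorm_floor <- function(k, mean, sd, floor_ms) {
    pmax(floor_ms, stats::rnorm(k, mean, sd))
  }

  ut <- conversation$utterances
  tg <- conversation$targets

  if (params$background == "speaker_following") {
    fl <- rnorm_floor(nrow(ut) - 1L, params$follow_latency_mean,
                      params$follow_latency_sd, params$follow_latency_floor_ms)
    ev_t <- c(0, snap_up(ut$onset_ms[-1L] + fl))
    ev_a <- ut$speaker
  } else {
    side <- sample(c("LEFT", "RIGHT"), 1L)
    t <- 0
    ev_t <- numeric(0)
    ev_a <- character(0)
    while (t < dur) {
      ev_t <- c(ev_t, snap_up(t))
      ev_a <- c(ev_a, side)
      side <- other_side(side)
      t <- t + stats::rexp(1L, 1 / params$mean_dwell_ms)
    }
  }

  p_sw <- unname(params$switch_prob[tg$condition])
  intended <- stats::runif(nrow(tg)) < p_sw
  sw_lat <- rnorm_floor(nrow(tg), params$switch_latency_mean,
                        params$switch_latency_sd,
                        params$switch_latency_floor_ms)
  sw_t <- snap_up(tg$silence_onset_ms + sw_lat)
  ev_t <- c(ev_t, sw_t[intended])
  ev_a <- c(ev_a, tg$responder[intended])

  o <- order(ev_t)
  ev_t <- ev_t[o]
  ev_a <- ev_a[o]
  keep <- !duplicated(ev_t, fromLast = TRUE) # later-planned event wins a tie
  ev_t <- ev_t[keep]
  ev_a <- ev_a[keep]

  # noise-free timeline and ground truth
  base <- data.frame(aoi = ev_a, onset_ms = ev_t,
                     offset_ms = c(ev_t[-1L], dur), stringsAsFactors = FALSE)
  base <- base[base$offset_ms > base$onset_ms, , drop = FALSE]
  base <- merge_fixation_runs(base, 0) # collapse adjacent same-AOI segments
  wins <- analysis_windows(conversation, params$group, leads)
  truth <- detect_windows(merge_fixation_runs(base, gap_tolerance_ms), wins,
                          min_fix_ms)

  # sampled AOI stream with lapses and dropout
  aoi <- ev_a[findInterval(times, ev_t)]
  n_lapse <- stats::rpois(1L, params$lapse_rate_hz * dur / 1000)
  if (n_lapse > 0L) {
    ls <- stats::runif(n_lapse, 0, dur)
    ld <- stats::rexp(n_lapse, 1 / params$lapse_mean_ms)
    la <- ifelse(stats::runif(n_lapse) < params$lapse_p_offscreen,
                 "OFFSCREEN", "OTHER")
    for (i in seq_len(n_lapse)) {
      aoi[times >= ls[i] & times < ls[i] + ld[i]] <- la[i]
    }
  }
  invalid <- stats::runif(n) < params$dropout_rate
  aoi[invalid] <- "OFFSCREEN"

  xy <- aoi_to_xy(aoi, layout)
  offscreen <- aoi == "OFFSCREEN"
  samples <- data.frame(
    participant_id = participant_id,
    group = params$group,
    conversation_id = conversation$id,
    trial_index = as.integer(trial_index),
    time_ms = times,
    validity_left = ifelse(offscreen, 4L, 0L),
    validity_right = ifelse(offscreen, 4L, 0L),
    x = ifelse(offscreen, NA_real_, xy$x),
    y = ifelse(offscreen, NA_real_, xy$y),
    stringsAsFactors = FALSE
  )
  truth_df <- data.frame(
    participant_id = participant_id,
    group = params$group,
    conversation_id = conversation$id,
    trial_index = as.integer(trial_index),
    item_id = tg$item_id,
    condition = tg$condition,
    outcome = tg$outcome,
    intended = intended,
    truth = truth,
    stringsAsFactors = FALSE
  )
  list(samples = samples, truth = truth_df)
}

#' Cohort specification for the synthetic generator
#'
#' Cohort sizes default to the emulated study's retained Dutch samples
#' (21 toddlers, 16 adults).
#'
#' @param n_toddlers,n_adults group sizes.
#' @param design an `experiment_design`, or `NULL` to generate one from the
#'   seed.
#' @param params_toddler,params_adult [sim_params()] per group.
#' @param seed master seed; design, cohort and trial randomness all derive
#'   from it.
#' @return A list of class `cohort_spec`.
#' @export
cohort_spec <- function(n_toddlers = 21L, n_adults = 16L, design = NULL,
                        params_toddler = sim_params("TODDLER"),
                        params_adult = sim_params("ADULT"),
                        seed = 1L) {
  check_that(n_toddlers >= 0L && n_adults >= 0L, "cohort sizes must be >= 0")
  structure(
    list(n_toddlers = as.integer(n_toddlers), n_adults = as.integer(n_adults),
         design = design, params_toddler = params_toddler,
         params_adult = params_adult, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

#' Simulate a full cohort of gaze recordings
#'
#' One trial per participant x conversation, with participants alternating
#' between the two presentation orders. Deterministic given the spec's seed.
#'
#' @param spec a [cohort_spec()].
#' @param leads,min_fix_ms,gap_tolerance_ms,layout see [sample_gaze_trial()].
#' @return A list with the `design`, the combined `samples` gaze table and
#'   the `truth` table (with `presentation_index` aligned to the trials).
#' @export
simulate_cohort <- function(spec, leads = GROUP_LEADS_MS, min_fix_ms = 100,
                            gap_tolerance_ms = 75,
                            layout = default_aoi_layout()) {
  seeds <- substream_seeds(spec$seed, c("design", "cohort"))
  design <- spec$design %||% generate_design(seeds[["design"]])
  violations <- validate_design(design)
  check_that(length(violations) == 0L,
             paste0("cohort design is invalid: ", paste(violations, collapse = "; ")))

  roster <- data.frame(
    participant_id = c(sprintf("T%02d", seq_len(spec$n_toddlers)),
                       sprintf("A%02d", seq_len(spec$n_adults))),
    group = c(rep("TODDLER", spec$n_toddlers), rep("ADULT", spec$n_adults)),
    stringsAsFactors = FALSE
  )
  roster$version <- rep_len(c("A", "B"), nrow(roster))

  with_local_seed(seeds[["cohort"]], {
    all_samples <- vector("list", nrow(roster) * 8L)
    all_truth <- vector("list", nrow(roster) * 8L)
    k <- 0L
    for (i in seq_len(nrow(roster))) {
      params <- if (roster$group[i] == "TODDLER") spec$params_toddler else spec$params_adult
      ord <- design$presentation_orders[[roster$version[i]]]
      for (idx in seq_len(8L)) {
        conv <- design$conversations[[ord[idx]]]
        trial <- sample_gaze_trial(conv, params, roster$participant_id[i],
                                   trial_index = idx, leads = leads,
                                   min_fix_ms = min_fix_ms,
                                   gap_tolerance_ms = gap_tolerance_ms,
                                   layout = layout)
        k <- k + 1L
        all_samples[[k]] <- trial$samples
        all_truth[[k]] <- trial$truth
      }
    }
    samples <- do.call(rbind, all_samples)
    truth <- do.call(rbind, all_truth)
    rownames(samples) <- rownames(truth) <- NULL
    names(truth)[names(truth) == "trial_index"] <- "presentation_index"
    list(design = design, samples = samples, truth = truth)
  })
}
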