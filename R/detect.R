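# Anticipatory gaze-switch detection. An analysis window is centered on a
# target 500 ms silence and extended by the group anticipation lead (300 ms
# for toddlers, 200 ms for adults) on each side. A switch is anticipatory
# when (1) the participant fixates the prior speaker for at least 100 ms at
# the end of the prior turn, (2) sometime thereafter fixates the upcoming
# responder for at least 100 ms, and (3) that responder fixation is initiated
# no later than the group lead after the response-turn onset (the silence
# offset). All intervals are half-open [onset, offset).

GROUP_LEADS_MS <- c(TODDLER = 300, ADULT = 200)

#' Group-specific anticipation lead
#'
#' The longest latency at which a gaze shift after the response-turn onset
#' still counts as anticipatory (planned before the response could be reacted
#' to): 300 ms for toddlers, 200 ms for adults.
#'
#' @param group `"TODDLER"` or `"ADULT"` (vectorized).
#' @param leads named lead vector, override to reconfigure.
#' @return Lead in ms.
#' @export
group_lead_ms <- function(group, leads = GROUP_LEADS_MS) {
  out <- unname(leads[group])
  check_that(!anyNA(out),
             paste0("unknown group(s): ",
                    paste(unique(group[is.na(out)]), collapse = ", ")))
  out
}

#' Build the analysis window for a target event
#'
#' The window is `[silence_onset - lead, silence_offset + lead]`, clipped to
#' the conversation `[0, duration]`; the response onset is the silence offset
#' and the initiation deadline is `response_onset + lead` (clipped with the
#' window).
#'
#' @param silence_onset_ms,silence_offset_ms the 500 ms target silence.
#' @param prior_speaker,responder AOI sides (`"LEFT"`/`"RIGHT"`).
#' @param group participant group, sets the lead via [group_lead_ms()].
#' @param duration_ms conversation duration for clipping.
#' @param leads optional lead override, see [group_lead_ms()].
#' @return A one-row data frame with `start_ms`, `end_ms`,
#'   `silence_onset_ms`, `silence_offset_ms`, `response_onset_ms`,
#'   `deadline_ms`, `prior_speaker`, `responder`, `group_lead_ms`.
#' @examples
#' build_analysis_window(10000, 10500, "LEFT", "RIGHT", "TODDLER", 30000)
#' @export
build_analysis_window <- function(silence_onset_ms, silence_offset_ms,
                                  prior_speaker, responder, group,
                                  duration_ms, leads = GROUP_LEADS_MS) {
  check_that(all(silence_offset_ms - silence_onset_ms == SILENCE_MS),
             "target silences must be exactly 500 ms")
  check_that(all(prior_speaker != responder),
             "responder must differ from the prior speaker")
  lead <- group_lead_ms(group, leads)
  start <- pmax(0, silence_onset_ms - lead)
  end <- pmin(duration_ms, silence_offset_ms + lead)
  data.frame(
    start_ms = start,
    end_ms = end,
    silence_onset_ms = silence_onset_ms,
    silence_offset_ms = silence_offset_ms,
    response_onset_ms = silence_offset_ms,
    deadline_ms = pmin(silence_offset_ms + lead, end),
    prior_speaker = prior_speaker,
    responder = responder,
    group_lead_ms = lead,
    stringsAsFactors = FALSE
  )
}

#' Analysis windows for all targets of a conversation
#'
#' @param conversation one conversation from an `experiment_design`.
#' @param group participant group.
#' @param leads optional lead override.
#' @return A data frame with one window per target, carrying `item_id`,
#'   `condition`, `outcome` and `target_index` alongside the window columns.
#' @export
analysis_windows <- function(conversation, group, leads = GROUP_LEADS_MS) {
  tg <- conversation$targets
  w <- build_analysis_window(tg$silence_onset_ms, tg$silence_offset_ms,
                             tg$prior_speaker, tg$responder, group,
                             conversation$duration_ms, leads)
  cbind(data.frame(target_index = seq_len(nrow(tg)), item_id = tg$item_id,
                   condition = tg$condition, outcome = tg$outcome,
                   stringsAsFactors = FALSE), w)
}

# Core detector on one window given fixation vectors. Relies on the pairwise
# criteria coupling only through F1's offset: if any qualifying prior-speaker
# fixation exists, the minimal qualifying offset admits every responder
# fixation any other qualifying F1 would admit.
detect_core <- function(onset, offset, aoi, dur, wstart, silence_onset,
                        deadline, prior, responder, min_fix_ms, strict_prior) {
  if (strict_prior) {
    f1 <- aoi == prior & dur >= min_fix_ms &
      onset <= silence_onset - min_fix_ms & offset >= silence_onset
  } else {
    f1 <- aoi == prior & dur >= min_fix_ms &
      onset < silence_onset & offset > wstart
  }
  if (!any(f1)) return(0L)
  m <- min(offset[f1])
  f2 <- aoi == responder & dur >= min_fix_ms & onset >= m & onset <= deadline
  if (!any(f2)) return(0L)
  1L
}

#' Decide whether a trial shows an anticipatory switch for one target
#'
#' Applies the three-criterion checklist to the trial's fixation sequence:
#' (1) a prior-speaker fixation of at least `min_fix_ms` overlapping the
#' pre-silence part of the window (with `strict_prior = TRUE`, the fixation
#' must cover the final `min_fix_ms` of the prior turn instead), (2) a later
#' responder fixation of at least `min_fix_ms`, (3) initiated (fixation
#' onset) no later than the window deadline.
#'
#' @param fixations a fixation data frame from [segment_fixations()].
#' @param window a one-row window data frame from [build_analysis_window()].
#' @param min_fix_ms minimum dwell (default 100 ms).
#' @param strict_prior stricter reading of "at the end of the prior turn".
#' @param details if `TRUE`, also return the initiation time.
#' @return 0/1, or with `details = TRUE` a list with `anticipatory` and
#'   `initiation_ms` (`NA` when no switch was found).
#' @export
detect_anticipatory_switch <- function(fixations, window, min_fix_ms = 100,
                                       strict_prior = FALSE, details = FALSE) {
  onset <- fixations$onset_ms
  offset <- fixations$offset_ms
  aoi <- fixations$aoi
  dur <- offset - onset
  hit <- detect_core(onset, offset, aoi, dur, window$start_ms,
                     window$silence_onset_ms, window$deadline_ms,
                     window$prior_speaker, window$responder,
                     min_fix_ms, strict_prior)
  if (!details) return(hit)
  init <- NA_real_
  if (hit == 1L) {
    f1 <- if (strict_prior) {
      aoi == window$prior_speaker & dur >= min_fix_ms &
        onset <= window$silence_onset_ms - min_fix_ms &
        offset >= window$silence_onset_ms
    } else {
      aoi == window$prior_speaker & dur >= min_fix_ms &
        onset < window$silence_onset_ms & offset > window$start_ms
    }
    m <- min(offset[f1])
    f2 <- aoi == window$responder & dur >= min_fix_ms & onset >= m &
      onset <= window$deadline_ms
    init <- min(onset[f2])
  }
  list(anticipatory = hit, initiation_ms = init)
}

#' Run the detector over many windows of one trial
#'
#' @param fixations fixation data frame for one trial.
#' @param windows a window data frame (one row per window), e.g. from
#'   [analysis_windows()] or [shuffle_windows()].
#' @param min_fix_ms,strict_prior see [detect_anticipatory_switch()].
#' @return Integer 0/1 vector, one element per window row.
#' @export
detect_windows <- function(fixations, windows, min_fix_ms = 100,
                           strict_prior = FALSE) {
  onset <- fixations$onset_ms
  offset <- fixations$offset_ms
  aoi <- fixations$aoi
  dur <- offset - onset
  nw <- nrow(windows)
  out <- integer(nw)
  wstart <- windows$start_ms
  so <- windows$silence_onset_ms
  dl <- windows$deadline_ms
  pr <- windows$prior_speaker
  rs <- windows$responder
  for (j in seq_len(nw)) {
    out[j] <- detect_core(onset, offset, aoi, dur, wstart[j], so[j], dl[j],
                          pr[j], rs[j], min_fix_ms, strict_prior)
  }
  out
}
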