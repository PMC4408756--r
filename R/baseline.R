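# Shuffled-window chance baseline. Under the null hypothesis that gaze
# switching is random, the detector should fire equally often whether its
# analysis windows sit on the real turn transitions or anywhere else in the
# stimulus. Each conversation's windows are therefore repositioned uniformly
# at random 100 times (lengths, speaker roles and internal deadline geometry
# preserved); the mean detector output over the 100 replicates is the chance
# rate for that target, and the corrected score is observed minus chance.

#' Randomly reposition a conversation's analysis windows
#'
#' Draws `n_reps` replicate placements of the conversation's analysis
#' windows. Each shuffled window keeps its original length (silence plus the
#' group lead on each side), its prior/responder roles and its internal
#' geometry (the nominal silence occupies the window center and the
#' initiation deadline is the window end), but its start is drawn uniformly
#' from `[0, duration - length]` in integer ms. Shuffled windows may overlap
#' each other and the real silences. Placement is deterministic given the
#' RNG state; seed before calling for reproducibility.
#'
#' @param conversation one conversation from an `experiment_design`.
#' @param group participant group (sets the window length via the lead).
#' @param n_reps number of replicate placements (default 100).
#' @param leads optional lead override, see [group_lead_ms()].
#' @return A data frame of shuffled windows with `replicate`, `target_index`,
#'   `item_id` and the window columns of [build_analysis_window()].
#' @export
shuffle_windows <- function(conversation, group, n_reps = 100L,
                            leads = GROUP_LEADS_MS) {
  check_that(n_reps >= 1L, "n_reps must be at least 1")
  tg <- conversation$targets
  k <- nrow(tg)
  lead <- group_lead_ms(group, leads)
  len <- SILENCE_MS + 2L * lead
  dur <- conversation$duration_ms
  if (len > dur) {
    stop(sprintf("analysis window (%d ms) longer than conversation %s (%d ms)",
                 len, conversation$id, dur), call. = FALSE)
  }
  n <- n_reps * k
  starts <- pmin(floor(stats::runif(n, 0, dur - len + 1)), dur - len)
  data.frame(
    replicate = rep(seq_len(n_reps), each = k),
    target_index = rep(seq_len(k), times = n_reps),
    item_id = rep(tg$item_id, times = n_reps),
    start_ms = starts,
    end_ms = starts + len,
    silence_onset_ms = starts + lead,
    silence_offset_ms = starts + lead + SILENCE_MS,
    response_onset_ms = starts + lead + SILENCE_MS,
    deadline_ms = starts + len,
    prior_speaker = rep(tg$prior_speaker, times = n_reps),
    responder = rep(tg$responder, times = n_reps),
    group_lead_ms = lead,
    stringsAsFactors = FALSE
  )
}

#' Chance rate of anticipatory switches per target
#'
#' Runs the detector over every shuffled window of a trial and averages the
#' 0/1 outcomes over replicates, yielding one baseline estimate of random
#' switching per original target.
#'
#' @param fixations a trial's fixation data frame.
#' @param shuffled a shuffled-window data frame from [shuffle_windows()].
#' @param min_fix_ms,strict_prior see [detect_anticipatory_switch()].
#' @return Numeric vector of rates in `[0, 1]`, ordered by `target_index`.
#' @export
baseline_rate <- function(fixations, shuffled, min_fix_ms = 100,
                          strict_prior = FALSE) {
  hits <- detect_windows(fixations, shuffled, min_fix_ms, strict_prior)
  as.numeric(tapply(hits, shuffled$target_index, mean))
}

#' Baseline-corrected anticipatory switch score
#'
#' @param actual observed 0/1 anticipation indicator(s).
#' @param baseline chance rate(s) in `[0, 1]`.
#' @return `actual - baseline`, in `[-1, 1]`.
#' @examples
#' corrected_score(1, 0.25) # 0.75
#' @export
corrected_score <- function(actual, baseline) {
  check_that(all(actual %in% c(0, 1)), "actual must be 0 or 1")
  if (any(baseline < 0 | baseline > 1 | is.na(baseline))) {
    stop("baseline rates must lie in [0, 1]", call. = FALSE)
  }
  actual - baseline
}

#' Score every target of every retained trial
#'
#' The central scoring step: segments each retained trial into fixations,
#' applies the detector to the real analysis windows (observed 0/1), applies
#' it to the shuffled windows (chance baseline), and subtracts. Shuffled
#' placements are drawn once per conversation x group and reused for every
#' participant, so all participants are scored against the same 100 replicate
#' placements; set `per_participant = TRUE` to redraw per participant.
#'
#' @param samples retained sample data frame with resolved AOIs.
#' @param design the `experiment_design` the stimuli follow.
#' @param n_shuffles number of shuffled placements (default 100).
#' @param min_fix_ms,gap_tolerance_ms,strict_prior detector settings.
#' @param leads group lead override, see [group_lead_ms()].
#' @param seed seed for the shuffled placements.
#' @param per_participant draw fresh placements for every participant.
#' @return The observation table: one row per participant x target with
#'   `participant_id`, `group`, `conversation_id`, `presentation_index`,
#'   `item_id`, `condition`, `outcome`, `actual`, `baseline`, `corrected`,
#'   plus -1/+1 model codes (`syn_code`, `pros_code`, `group_code`,
#'   `change_code`; `change_code` is `NA` for syntactically incomplete items).
#' @export
compute_switch_observations <- function(samples, design, n_shuffles = 100L,
                                        min_fix_ms = 100,
                                        gap_tolerance_ms = 75,
                                        strict_prior = FALSE,
                                        leads = GROUP_LEADS_MS,
                                        seed = 1L,
                                        per_participant = FALSE) {
  check_that(!is.null(samples$aoi), "samples must have resolved AOIs")
  conv_ids <- vapply(design$conversations, `[[`, "", "id")
  groups <- names(leads)

  real_windows <- list()
  shuffled <- list()
  with_local_seed(seed, {
    for (ci in seq_along(design$conversations)) {
      cv <- design$conversations[[ci]]
      for (g in groups) {
        key <- paste(cv$id, g, sep = "\r")
        real_windows[[key]] <- analysis_windows(cv, g, leads)
        if (!per_participant) {
          shuffled[[key]] <- shuffle_windows(cv, g, n_shuffles, leads)
        }
      }
    }
    recs <- trial_recordings(samples)
    rows <- lapply(recs, function(rec) {
      ci <- match(rec$conversation_id, conv_ids)
      check_that(!is.na(ci), paste0("samples reference unknown conversation: ",
                                    rec$conversation_id))
      cv <- design$conversations[[ci]]
      key <- paste(cv$id, rec$group, sep = "\r")
      fix <- segment_fixations(rec$samples$time_ms, rec$samples$aoi,
                               gap_tolerance_ms)
      rw <- real_windows[[key]]
      sh <- if (per_participant) {
        shuffle_windows(cv, rec$group, n_shuffles, leads)
      } else {
        shuffled[[key]]
      }
      actual <- detect_windows(fix, rw, min_fix_ms, strict_prior)
      base <- baseline_rate(fix, sh, min_fix_ms, strict_prior)
      data.frame(
        participant_id = rec$participant_id,
        group = rec$group,
        conversation_id = rec$conversation_id,
        presentation_index = rec$trial_index,
        item_id = rw$item_id,
        condition = rw$condition,
        outcome = rw$outcome,
        actual = actual,
        baseline = base,
        corrected = corrected_score(actual, base),
        stringsAsFactors = FALSE,
        row.names = NULL
      )
    })
    obs <- do.call(rbind, rows)
    rownames(obs) <- NULL
    add_contrast_codes(obs)
  })
}
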