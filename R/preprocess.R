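# Trial- and participant-level exclusion: a trial is excluded when the
# participant attended to the screen for less than 75% of its duration
# (strict inequality: exactly 75% is retained); a participant is excluded
# entirely when more than four of their trials were excluded.

sample_dwell_ms <- function(time_ms) {
  n <- length(time_ms)
  if (n == 1L) return(0)
  d <- diff(time_ms)
  c(d, stats::median(d)) # last sample gets the median inter-sample interval
}

#' Fraction of a trial spent attending to the screen
#'
#' Computed on the time axis: each sample's dwell is the interval to the next
#' sample (the last sample gets the median interval), and a sample counts as
#' on screen when its resolved AOI is LEFT, RIGHT or OTHER.
#'
#' @param time_ms sample timestamps (ms, strictly increasing).
#' @param aoi resolved AOI labels, see [resolve_aoi()].
#' @return On-screen fraction in `[0, 1]`.
#' @examples
#' attention_fraction(c(0, 20, 40, 60), c("LEFT", "LEFT", "OFFSCREEN", "OFFSCREEN"))
#' @export
attention_fraction <- function(time_ms, aoi) {
  check_that(length(time_ms) > 0L, "attention_fraction: empty trial")
  check_that(length(time_ms) == length(aoi),
             "time_ms and aoi must have the same length")
  d <- sample_dwell_ms(time_ms)
  if (sum(d) == 0) return(as.numeric(all(aoi != "OFFSCREEN")))
  sum(d[aoi != "OFFSCREEN"]) / sum(d)
}

#' Per-trial attention table
#'
#' @param samples a sample data frame with resolved AOIs (see
#'   [resolve_sample_aois()]); AOIs are resolved on the fly if absent.
#' @param layout,valid_codes passed to [resolve_sample_aois()] when needed.
#' @return A data frame with one row per participant x conversation:
#'   `participant_id`, `group`, `conversation_id`, `trial_index`,
#'   `on_screen_fraction`.
#' @export
attention_table <- function(samples, layout = default_aoi_layout(),
                            valid_codes = c(0L, 1L)) {
  samples <- resolve_sample_aois(samples, layout, valid_codes)
  recs <- trial_recordings(samples)
  do.call(rbind, lapply(recs, function(r) {
    data.frame(
      participant_id = r$participant_id,
      group = r$group,
      conversation_id = r$conversation_id,
      trial_index = r$trial_index,
      on_screen_fraction = attention_fraction(r$samples$time_ms, r$samples$aoi),
      stringsAsFactors = FALSE,
      row.names = NULL
    )
  }))
}

#' Apply the trial-level attention exclusion
#'
#' Flags trials whose on-screen fraction is strictly below the threshold.
#'
#' @param attention a trial table from [attention_table()].
#' @param threshold attention threshold (default 0.75; a trial at exactly the
#'   threshold is retained).
#' @return `attention` with a logical `excluded` column.
#' @export
apply_trial_exclusion <- function(attention, threshold = 0.75) {
  check_that(threshold > 0, "attention threshold must be positive")
  attention$excluded <- attention$on_screen_fraction < threshold
  attention
}

#' Apply the participant-level exclusion
#'
#' Participants with more than `max_excluded` excluded trials are dropped
#' entirely (general inattention to the stimuli); a participant with exactly
#' `max_excluded` excluded trials is retained.
#'
#' @param attention a trial table with an `excluded` column, see
#'   [apply_trial_exclusion()].
#' @param max_excluded maximum tolerated number of excluded trials (default 4).
#' @return The audit table: `attention` with `n_excluded_trials` and
#'   `participant_excluded` columns added.
#' @export
apply_participant_exclusion <- function(attention, max_excluded = 4L) {
  check_that(!is.null(attention$excluded),
             "run apply_trial_exclusion() first (no 'excluded' column)")
  n_exc <- tapply(attention$excluded, attention$participant_id, sum)
  attention$n_excluded_trials <- as.integer(n_exc[attention$participant_id])
  attention$participant_excluded <- attention$n_excluded_trials > max_excluded
  attention
}

#' Build the exclusion audit and filter a sample table
#'
#' Runs the full exclusion chain (attention fractions, trial exclusion,
#' participant exclusion, plus an input-level drop list for e.g. equipment
#' errors) and partitions the samples into retained and excluded trials.
#'
#' @param samples sample data frame.
#' @param layout,valid_codes AOI resolution settings.
#' @param threshold attention threshold, see [apply_trial_exclusion()].
#' @param max_excluded see [apply_participant_exclusion()].
#' @param drop_participants participant ids dropped before any computation
#'   (equipment errors are recorded as data, not recomputed).
#' @return A list with `audit` (the per-trial audit table), `kept` and
#'   `excluded` (sample data frames partitioning the input).
#' @export
preprocess_samples <- function(samples, layout = default_aoi_layout(),
                               valid_codes = c(0L, 1L), threshold = 0.75,
                               max_excluded = 4L,
                               drop_participants = character(0)) {
  dropped <- samples$participant_id %in% drop_participants
  samples <- resolve_sample_aois(samples[!dropped, , drop = FALSE],
                                 layout, valid_codes)
  audit <- attention_table(samples, layout, valid_codes)
  audit <- apply_trial_exclusion(audit, threshold)
  audit <- apply_participant_exclusion(audit, max_excluded)
  bad <- audit[audit$excluded | audit$participant_excluded, , drop = FALSE]
  bad_key <- paste(bad$participant_id, bad$conversation_id, sep = "\r")
  key <- paste(samples$participant_id, samples$conversation_id, sep = "\r")
  keep <- !(key %in% bad_key)
  list(
    audit = audit,
    kept = samples[keep, , drop = FALSE],
    excluded = samples[!keep, , drop = FALSE]
  )
}
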