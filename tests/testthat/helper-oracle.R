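# Independent brute-force reference for the switch detector: enumerate every
# (F1, F2) fixation pair and apply the three criteria literally. Kept free of
# any shared code with the package detector.
brute_force_detect <- function(fixations, window, min_fix_ms = 100,
                               strict_prior = FALSE) {
  on <- fixations$onset_ms
  off <- fixations$offset_ms
  aoi <- fixations$aoi
  d <- off - on
  prior <- window$prior_speaker
  resp <- window$responder
  so <- window$silence_onset_ms
  ws <- window$start_ms
  dl <- window$deadline_ms
  for (i in seq_along(on)) {
    ok1 <- aoi[i] == prior && d[i] >= min_fix_ms &&
      (if (strict_prior) on[i] <= so - min_fix_ms && off[i] >= so
       else on[i] < so && off[i] > ws)
    if (!ok1) next
    for (j in seq_along(on)) {
      if (aoi[j] == resp && d[j] >= min_fix_ms &&
          on[j] >= off[i] && on[j] <= dl) {
        return(1L)
      }
    }
  }
  0L
}

# Random contiguous fixation sequence over the four AOI labels (consecutive
# fixations always differ, as segmentation guarantees).
random_fixations <- function(n_fix, t0 = 9000,
                             aois = c("LEFT", "RIGHT", "OTHER", "OFFSCREEN"),
                             dur_range = c(20L, 600L)) {
  durs <- sample(seq(dur_range[1], dur_range[2]), n_fix, replace = TRUE)
  onsets <- t0 + cumsum(c(0L, durs[-n_fix]))
  a <- character(n_fix)
  a[1] <- sample(aois, 1)
  if (n_fix > 1) {
    for (i in 2:n_fix) a[i] <- sample(setdiff(aois, a[i - 1]), 1)
  }
  data.frame(aoi = a, onset_ms = onsets, offset_ms = onsets + durs,
             stringsAsFactors = FALSE)
}

# Random analysis window roughly overlapping the fixation span.
random_window <- function(t0 = 9000) {
  group <- sample(c("TODDLER", "ADULT"), 1)
  silence_onset <- t0 + sample(0:2500, 1)
  prior <- sample(c("LEFT", "RIGHT"), 1)
  build_analysis_window(silence_onset, silence_onset + 500,
                        prior_speaker = prior,
                        responder = setdiff(c("LEFT", "RIGHT"), prior),
                        group = group, duration_ms = 40000)
}
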