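# AOI fixation segmentation: maximal constant-AOI dwell runs on the time
# axis, with short interruptions bridged. Sample i covers the half-open
# interval [t_i, t_{i+1}); the last sample covers one median inter-sample
# interval. Runs of the same AOI separated by at most `gap_tolerance_ms` of
# other material are merged (tracker recovery gaps are shorter than 100 ms,
# so the default tolerance of 75 ms bridges single dropped samples at 50 Hz
# without bridging genuine looks away).

# merge same-AOI runs across gaps <= tol; runs is a data.frame(aoi, onset_ms,
# offset_ms) of time-contiguous dwell segments. Shared by the sample-level
# segmentation and the synthetic generator's ground-truth evaluation.
merge_fixation_runs <- function(runs, gap_tolerance_ms) {
  n <- nrow(runs)
  if (n <= 1L) return(runs)
  aoi <- runs$aoi
  onset <- runs$onset_ms
  offset <- runs$offset_ms
  out_aoi <- character(n)
  out_on <- numeric(n)
  out_off <- numeric(n)
  k <- 0L
  for (i in seq_len(n)) {
    merged <- FALSE
    j <- k
    while (j >= 1L) {
      gap <- onset[i] - out_off[j]
      if (gap > gap_tolerance_ms) break
      if (out_aoi[j] == aoi[i]) {
        out_off[j] <- offset[i] # absorb the gap and anything inside it
        k <- j
        merged <- TRUE
        break
      }
      j <- j - 1L
    }
    if (!merged) {
      k <- k + 1L
      out_aoi[k] <- aoi[i]
      out_on[k] <- onset[i]
      out_off[k] <- offset[i]
    }
  }
  data.frame(aoi = out_aoi[seq_len(k)], onset_ms = out_on[seq_len(k)],
             offset_ms = out_off[seq_len(k)], stringsAsFactors = FALSE)
}

#' Segment resolved AOI samples into fixations
#'
#' Produces the full dwell sequence: maximal runs of a constant AOI label,
#' with same-AOI runs separated by a gap of at most `gap_tolerance_ms`
#' merged (the gap and any short intervening material are absorbed).
#' No minimum-duration filtering is applied here; the 100 ms dwell criterion
#' is enforced by the switch detector.
#'
#' @param time_ms strictly increasing sample timestamps (ms).
#' @param aoi per-sample AOI labels.
#' @param gap_tolerance_ms maximum bridged gap (default 75 ms).
#' @return A data frame of fixations: `aoi`, `onset_ms`, `offset_ms`
#'   (half-open intervals); consecutive rows have distinct AOIs.
#' @examples
#' segment_fixations(c(0, 50, 100, 150), c("LEFT", "LEFT", "RIGHT", "RIGHT"))
#' @export
segment_fixations <- function(time_ms, aoi, gap_tolerance_ms = 75) {
  check_that(length(time_ms) == length(aoi),
             "time_ms and aoi must have the same length")
  check_that(length(time_ms) > 0L, "segment_fixations: empty trial")
  check_that(gap_tolerance_ms >= 0, "gap tolerance must be non-negative")
  n <- length(time_ms)
  d <- sample_dwell_ms(time_ms)
  end_times <- time_ms + d
  r <- rle(aoi)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  runs <- data.frame(
    aoi = r$values,
    onset_ms = time_ms[starts],
    offset_ms = end_times[ends],
    stringsAsFactors = FALSE
  )
  merge_fixation_runs(runs, gap_tolerance_ms)
}
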