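# Published exclusion and pre-test counts from the two emulated experiments
# (Dutch and English). These are inputs recorded as data — the raw recordings
# were never deposited, so the only checkable quantities are percentages that
# are pure arithmetic on the printed counts.

#' Published exclusion and pre-test counts
#'
#' One row per reported percentage, with the printed numerator, the total it
#' was taken against, the percentage as printed and the number of decimal
#' digits it was printed with. Trial-level totals are the retained trial
#' count plus the excluded trials, the only totals consistent with the
#' printed percentages.
#'
#' @return A data frame with columns `experiment`, `quantity`, `count`,
#'   `total`, `printed_pct`, `digits`.
#' @seealso [exclusion_percentages()]
#' @export
reported_counts <- function() {
  data.frame(
    experiment = c("dutch", "dutch", "dutch", "english", "english"),
    quantity = c(
      "toddlers_excluded_inattention",
      "trials_excluded",
      "ambiguous_prosody_targets",
      "toddlers_excluded_inattention",
      "trials_excluded"
    ),
    count = c(11L, 27L, 11L, 4L, 27L),
    total = c(33L, 1056L + 27L, 32L, 25L, 1144L + 27L),
    printed_pct = c(33, 2.5, 34, 16, 2.3),
    digits = c(0L, 1L, 0L, 0L, 1L),
    stringsAsFactors = FALSE
  )
}

#' Recompute the published percentages from their counts
#'
#' @param counts a data frame in the format of [reported_counts()].
#' @return `counts` with `recomputed_pct` (count/total, rounded to the
#'   printed precision) and a logical `matches_printed` column.
#' @examples
#' exclusion_percentages()
#' @export
exclusion_percentages <- function(counts = reported_counts()) {
  counts$recomputed_pct <- round(100 * counts$count / counts$total,
                                 counts$digits)
  counts$matches_printed <- counts$recomputed_pct == counts$printed_pct
  counts
}
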