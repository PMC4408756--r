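# Eye-tracker sample IO: delimited sample exports, per-eye validity handling,
# and classification of samples into areas of interest (AOIs). The two puppets
# occupy the left and right screen halves; gaze is classified as LEFT, RIGHT,
# OTHER (on screen, neither puppet) or OFFSCREEN. All downstream operations
# consume milliseconds, never sample counts, so 50 Hz and 120 Hz recordings
# are handled identically.

#' Construct an AOI layout
#'
#' Rectangles are given in normalized screen coordinates as
#' `c(xmin, xmax, ymin, ymax)` and treated as closed (boundary points belong
#' to the region). The two regions must be disjoint and inside the screen
#' bounds.
#'
#' @param left,right speaker regions.
#' @param screen screen bounds.
#' @return An object of class `aoi_layout`.
#' @examples
#' default_aoi_layout()
#' @export
aoi_layout <- function(left = c(0.02, 0.48, 0.05, 0.95),
                       right = c(0.52, 0.98, 0.05, 0.95),
                       screen = c(0, 1, 0, 1)) {
  for (r in list(left = left, right = right, screen = screen)) {
    check_that(length(r) == 4L && r[1] < r[2] && r[3] < r[4],
               "each region must be c(xmin, xmax, ymin, ymax) with min < max")
  }
  inside <- function(r, s) r[1] >= s[1] && r[2] <= s[2] && r[3] >= s[3] && r[4] <= s[4]
  check_that(inside(left, screen) && inside(right, screen),
             "AOI regions must lie inside the screen bounds")
  disjoint <- left[2] < right[1] || right[2] < left[1] ||
    left[4] < right[3] || right[4] < left[3]
  check_that(disjoint, "left and right AOI regions must be disjoint")
  structure(list(left = left, right = right, screen = screen),
            class = "aoi_layout")
}

#' @rdname aoi_layout
#' @export
default_aoi_layout <- function() aoi_layout()

#' Read or write an AOI layout config (YAML)
#'
#' @param path file path.
#' @param layout an `aoi_layout`.
#' @return `read_aoi_layout()` returns an `aoi_layout`.
#' @export
read_aoi_layout <- function(path) {
  doc <- yaml::read_yaml(path)
  aoi_layout(left = as.numeric(doc$left), right = as.numeric(doc$right),
             screen = as.numeric(doc$screen %||% c(0, 1, 0, 1)))
}

#' @rdname read_aoi_layout
#' @export
write_aoi_layout <- function(layout, path) {
  yaml::write_yaml(list(left = as.numeric(layout$left),
                        right = as.numeric(layout$right),
                        screen = as.numeric(layout$screen)), path)
  invisible(path)
}

GAZE_COLUMNS_COMMON <- c("participant_id", "group", "conversation_id",
                         "trial_index", "time_ms", "validity_left",
                         "validity_right")

#' Read an eye-tracker sample export
#'
#' Reads a delimited text export with one row per gaze sample. Two dialects
#' are supported: `"xy"` (normalized screen coordinates `x`, `y`; missing
#' coordinates allowed) and `"aoi"` (a pre-resolved `aoi` column with values
#' LEFT/RIGHT/OTHER/OFFSCREEN). Common required columns: `participant_id`,
#' `group` (TODDLER/ADULT), `conversation_id`, `trial_index` (presentation
#' position 1-8), `time_ms`, `validity_left`, `validity_right`. Timestamps
#' must be strictly increasing within each participant x conversation trial.
#'
#' @param path path to a CSV (comma) or TSV (tab; `.tsv`/`.tab`) file.
#' @param dialect column dialect, `"xy"` (default) or `"aoi"`.
#' @return A data frame of samples, one row per sample.
#' @seealso [trial_recordings()], [resolve_aoi()]
#' @export
read_gaze_table <- function(path, dialect = c("xy", "aoi")) {
  dialect <- match.arg(dialect)
  check_that(file.exists(path), paste0("gaze table not found: ", path))
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  required <- c(GAZE_COLUMNS_COMMON, if (dialect == "xy") c("x", "y") else "aoi")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0L) {
    stop(sprintf("gaze table '%s': missing required column(s): %s",
                 path, paste(missing, collapse = ", ")), call. = FALSE)
  }
  check_gaze_samples(df, path)
  df
}

# strictly increasing timestamps within each trial, in file order
check_gaze_samples <- function(df, where = "gaze table") {
  key <- paste(df$participant_id, df$conversation_id, sep = "\r")
  for (k in unique(key)) {
    idx <- which(key == k)
    t <- df$time_ms[idx]
    bad <- which(diff(t) <= 0)
    if (length(bad) > 0L) {
      row <- idx[bad[1L] + 1L]
      kind <- if (df$time_ms[row] == df$time_ms[idx[bad[1L]]]) "duplicated" else "non-monotone"
      stop(sprintf("%s: %s timestamp at row %d (participant %s, conversation %s, t=%s ms)",
                   where, kind, row, df$participant_id[row],
                   df$conversation_id[row], df$time_ms[row]), call. = FALSE)
    }
  }
  invisible(df)
}

#' Write a gaze sample table
#'
#' @param samples a sample data frame (see [read_gaze_table()]).
#' @param path output path; `.tsv`/`.tab` writes tab-separated, otherwise CSV.
#' @return `path`, invisibly.
#' @export
write_gaze_table <- function(samples, path) {
  sep <- if (grepl("\\.(tsv|tab)$", path, ignore.case = TRUE)) "\t" else ","
  utils::write.table(samples, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Infer the nominal sampling rate from timestamps
#'
#' The rate is the reciprocal of the median inter-sample interval, snapped to
#' the common tracker rates (50 or 120 Hz) when within 10%.
#'
#' @param time_ms sample timestamps in ms.
#' @return Nominal rate in Hz.
#' @export
infer_sampling_rate <- function(time_ms) {
  check_that(length(time_ms) >= 2L, "need at least two samples to infer a rate")
  rate <- 1000 / stats::median(diff(time_ms))
  for (nominal in c(50, 120)) {
    if (abs(rate - nominal) / nominal <= 0.1) return(nominal)
  }
  round(rate, 1)
}

#' Split a sample table into per-trial recordings
#'
#' @param samples a sample data frame.
#' @return A list with one element per participant x conversation, each a list
#'   with `participant_id`, `group`, `conversation_id`, `trial_index`,
#'   `nominal_rate_hz` and the `samples` data frame.
#' @export
trial_recordings <- function(samples) {
  key <- paste(samples$participant_id, samples$conversation_id, sep = "\r")
  idx <- split(seq_len(nrow(samples)), key)
  # preserve file order of first appearance
  idx <- idx[order(vapply(idx, min, 0L))]
  lapply(idx, function(i) {
    s <- samples[i, , drop = FALSE]
    rownames(s) <- NULL
    list(
      participant_id = s$participant_id[1L],
      group = s$group[1L],
      conversation_id = s$conversation_id[1L],
      trial_index = s$trial_index[1L],
      nominal_rate_hz = infer_sampling_rate(s$time_ms),
      samples = s
    )
  })
}

#' Per-sample validity: valid in at least one eye
#'
#' A sample counts as valid when the tracker marked the look as valid in at
#' least one eye, i.e. when either eye's validity code is in `valid_codes`.
#'
#' @param validity_left,validity_right per-eye validity codes.
#' @param valid_codes codes counted as valid (default `c(0, 1)`, as in common
#'   binocular exports where 0 = both eyes found, 1 = probably this eye).
#' @return Logical vector.
#' @examples
#' is_valid_sample(0, 4) # TRUE: valid in the left eye
#' @export
is_valid_sample <- function(validity_left, validity_right,
                            valid_codes = c(0L, 1L)) {
  (validity_left %in% valid_codes) | (validity_right %in% valid_codes)
}

#' Classify gaze samples into AOIs
#'
#' Invalid samples and samples with missing or off-screen coordinates map to
#' `OFFSCREEN`; points inside the left/right speaker rectangle (boundaries
#' included) map to `LEFT`/`RIGHT`; remaining on-screen points map to `OTHER`.
#' Every sample maps to exactly one of the four labels.
#'
#' @param x,y normalized gaze coordinates (may be `NA`).
#' @param valid logical per-sample validity, see [is_valid_sample()].
#' @param layout an [aoi_layout()].
#' @return Character vector over `{LEFT, RIGHT, OTHER, OFFSCREEN}`.
#' @export
resolve_aoi <- function(x, y, valid, layout = default_aoi_layout()) {
  n <- max(length(x), length(y), length(valid))
  x <- rep_len(as.numeric(x), n)
  y <- rep_len(as.numeric(y), n)
  valid <- rep_len(as.logical(valid), n)
  aoi <- rep("OFFSCREEN", n)
  s <- layout$screen
  on_screen <- valid & !is.na(x) & !is.na(y) &
    x >= s[1] & x <= s[2] & y >= s[3] & y <= s[4]
  in_rect <- function(r) {
    on_screen & x >= r[1] & x <= r[2] & y >= r[3] & y <= r[4]
  }
  aoi[on_screen] <- "OTHER"
  aoi[in_rect(layout$left)] <- "LEFT"
  aoi[in_rect(layout$right)] <- "RIGHT"
  aoi
}

#' Resolve AOIs for a whole sample table
#'
#' Convenience wrapper: applies the validity rule and [resolve_aoi()] to a
#' sample data frame. Tables in the `"aoi"` dialect (pre-resolved `aoi`
#' column) are returned with the column checked and passed through.
#'
#' @param samples sample data frame.
#' @param layout an [aoi_layout()].
#' @param valid_codes see [is_valid_sample()].
#' @return `samples` with an `aoi` column.
#' @export
resolve_sample_aois <- function(samples, layout = default_aoi_layout(),
                                valid_codes = c(0L, 1L)) {
  if ("aoi" %in% names(samples)) {
    bad <- setdiff(unique(samples$aoi), c("LEFT", "RIGHT", "OTHER", "OFFSCREEN"))
    check_that(length(bad) == 0L,
               paste0("pre-resolved aoi column contains unknown labels: ",
                      paste(bad, collapse = ", ")))
    return(samples)
  }
  valid <- is_valid_sample(samples$validity_left, samples$validity_right,
                           valid_codes)
  samples$aoi <- resolve_aoi(samples$x, samples$y, valid, layout)
  samples
}
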