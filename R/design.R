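# Stimulus design: eight 30-s dyadic conversations, each with six filler and
# four target utterances (one per completeness condition), all separated by
# 500 ms silences. Target utterances cross lexicosyntactic (+/-SYN) and
# prosodic (+/-PROS) completeness; syntactically incomplete targets are always
# followed by a continuation of the same speaker, while syntactically complete
# targets are followed by a speaker change half of the time.

#' Condition labels in canonical order
#' @keywords internal
#' @noRd
CONDITION_LEVELS <- c(
  "FULLY_INCOMPLETE", "INCOMPLETE_SYNTAX", "INCOMPLETE_PROSODY", "FULLY_COMPLETE"
)

#' The four target-utterance conditions
#'
#' Returns the factorial crossing of lexicosyntactic and prosodic completeness
#' with its canonical labels: `FULLY_INCOMPLETE` (-SYN -PROS),
#' `INCOMPLETE_SYNTAX` (-SYN +PROS), `INCOMPLETE_PROSODY` (+SYN -PROS) and
#' `FULLY_COMPLETE` (+SYN +PROS).
#'
#' @return A data frame with columns `label`, `syntax_complete`,
#'   `prosody_complete`.
#' @examples
#' condition_table()
#' @export
condition_table <- function() {
  data.frame(
    label = CONDITION_LEVELS,
    syntax_complete = c(FALSE, FALSE, TRUE, TRUE),
    prosody_complete = c(FALSE, TRUE, FALSE, TRUE),
    stringsAsFactors = FALSE
  )
}

#' Look up the label for a completeness pair, or the pair for a label
#'
#' @param syntax_complete,prosody_complete logical flags.
#' @return `condition_label()` returns the label; `condition_flags()` returns a
#'   one-row data frame with the two flags.
#' @examples
#' condition_label(TRUE, FALSE) # "INCOMPLETE_PROSODY"
#' @export
condition_label <- function(syntax_complete, prosody_complete) {
  tab <- condition_table()
  idx <- match(paste(syntax_complete, prosody_complete),
               paste(tab$syntax_complete, tab$prosody_complete))
  check_that(!anyNA(idx), "syntax/prosody flags must be logical TRUE/FALSE")
  tab$label[idx]
}

#' @rdname condition_label
#' @param label a condition label.
#' @export
condition_flags <- function(label) {
  tab <- condition_table()
  idx <- match(label, tab$label)
  check_that(!anyNA(idx),
             paste0("unknown condition label(s): ",
                    paste(unique(label[is.na(idx)]), collapse = ", ")))
  tab[idx, c("syntax_complete", "prosody_complete"), drop = FALSE]
}

# Silence inserted at every utterance boundary and after each target (ms).
SILENCE_MS <- 500L

# Target slot sets within the 10-utterance sequence: positions 2..9, pairwise
# at least two apart, so every target is followed by a filler whose speaker can
# encode the target outcome.
TARGET_SLOT_SETS <- list(
  c(2L, 4L, 6L, 8L), c(2L, 4L, 6L, 9L), c(2L, 4L, 7L, 9L),
  c(2L, 5L, 7L, 9L), c(3L, 5L, 7L, 9L)
)

# Global counterbalancing: per condition, the speaker (4 LEFT / 4 RIGHT across
# the 8 conversations) and, for +SYN conditions, the outcome (4 SWITCH / 4
# CONTINUE across the 8 conversations).
draw_global_assignment <- function() {
  tab <- condition_table()
  speaker <- matrix("RIGHT", nrow = 8L, ncol = 4L,
                    dimnames = list(NULL, CONDITION_LEVELS))
  outcome <- matrix("CONTINUE", nrow = 8L, ncol = 4L,
                    dimnames = list(NULL, CONDITION_LEVELS))
  for (lab in CONDITION_LEVELS) {
    speaker[sample.int(8L, 4L), lab] <- "LEFT"
    if (tab$syntax_complete[tab$label == lab]) {
      outcome[sample.int(8L, 4L), lab] <- "SWITCH"
    }
  }
  list(speaker = speaker, outcome = outcome)
}

# Build one conversation under the global speaker/outcome assignment.
# Rejection sampling over target order, slots, filler speakers and durations;
# returns NULL when no arrangement with 5-7 turn transitions is found.
build_conversation <- function(conv_index, assign, max_tries = 500L) {
  for (try in seq_len(max_tries)) {
    cond_order <- sample(CONDITION_LEVELS)
    slots <- TARGET_SLOT_SETS[[sample.int(length(TARGET_SLOT_SETS), 1L)]]

    speaker <- rep(NA_character_, 10L)
    outcome <- stats::setNames(rep(NA_character_, 4L), cond_order)
    conflict <- FALSE
    for (k in seq_len(4L)) {
      lab <- cond_order[k]
      sl <- slots[k]
      spk <- assign$speaker[conv_index, lab]
      out <- assign$outcome[conv_index, lab]
      nxt <- if (out == "SWITCH") other_side(spk) else spk
      if ((!is.na(speaker[sl]) && speaker[sl] != spk) ||
          (!is.na(speaker[sl + 1L]) && speaker[sl + 1L] != nxt)) {
        conflict <- TRUE
        break
      }
      speaker[sl] <- spk
      speaker[sl + 1L] <- nxt
      outcome[lab] <- out
    }
    if (conflict) next

    free <- which(is.na(speaker))
    speaker[free] <- sample(c("LEFT", "RIGHT"), length(free), replace = TRUE)
    n_transitions <- sum(speaker[-1L] != speaker[-10L])
    if (n_transitions < 5L || n_transitions > 7L) next

    # Durations: uniform draws rescaled so the conversation (last offset)
    # lands in [29.3, 30.7] s; gaps are always exactly 500 ms.
    base <- stats::runif(10L, 1500, 3500)
    total <- stats::runif(1L, 29300, 30700)
    durs <- as.integer(round(base * (total - 9L * SILENCE_MS) / sum(base)))
    onsets <- as.integer(cumsum(c(0L, durs[-10L] + SILENCE_MS)))
    offsets <- onsets + durs
    duration_ms <- offsets[10L]
    if (duration_ms < 29000L || duration_ms > 31000L) next

    is_target <- seq_len(10L) %in% slots
    condition <- rep(NA_character_, 10L)
    condition[slots] <- cond_order

    utterances <- data.frame(
      index = seq_len(10L),
      speaker = speaker,
      onset_ms = onsets,
      offset_ms = offsets,
      is_target = is_target,
      condition = condition,
      stringsAsFactors = FALSE
    )

    ord <- order(match(cond_order, CONDITION_LEVELS))
    targets <- data.frame(
      item_id = paste0("C", conv_index, "_", cond_order[ord]),
      condition = cond_order[ord],
      prior_speaker = speaker[slots[ord]],
      responder = other_side(speaker[slots[ord]]),
      silence_onset_ms = offsets[slots[ord]],
      silence_offset_ms = onsets[slots[ord] + 1L],
      outcome = unname(outcome[cond_order[ord]]),
      stringsAsFactors = FALSE
    )

    return(list(
      id = paste0("C", conv_index),
      duration_ms = duration_ms,
      n_transitions = n_transitions,
      utterances = utterances,
      targets = targets
    ))
  }
  NULL
}

#' Generate the eight-conversation experiment design
#'
#' Builds a full stimulus design: eight conversations of about 30 s, each with
#' six filler and four target utterances (one per condition), consecutive
#' utterances separated by exactly 500 ms of silence, five to seven turn
#' transitions per conversation, target utterances counterbalanced so that each
#' condition is spoken four times by each puppet across the experiment, and
#' exactly half of the syntactically complete targets followed by a speaker
#' change. Two presentation orders (experiment versions) are drawn.
#'
#' @param seed integer; the design is deterministic given the seed.
#' @return An object of class `experiment_design`: a list with `conversations`
#'   (each with `id`, `duration_ms`, `n_transitions`, an `utterances` data
#'   frame and a `targets` data frame), `presentation_orders` (two permutations
#'   of 1..8) and the `seed`.
#' @examples
#' d <- generate_design(1)
#' nrow(design_targets(d)) # 32
#' @seealso [validate_design()], [save_design()], [design_targets()]
#' @export
generate_design <- function(seed = 1L) {
  check_that(is.numeric(seed) && length(seed) == 1L && is.finite(seed),
             "seed must be a single finite number")
  with_local_seed(seed, {
    repeat {
      assign <- draw_global_assignment()
      conversations <- vector("list", 8L)
      ok <- TRUE
      for (ci in seq_len(8L)) {
        conv <- build_conversation(ci, assign)
        if (is.null(conv)) {
          ok <- FALSE
          break
        }
        conversations[[ci]] <- conv
      }
      if (ok) break
    }
    design <- structure(
      list(
        conversations = conversations,
        presentation_orders = list(A = sample.int(8L), B = sample.int(8L)),
        seed = as.integer(seed)
      ),
      class = "experiment_design"
    )
    design
  })
}

#' Flat table of all target events in a design
#'
#' @param design an `experiment_design`.
#' @return A data frame with one row per target event (32 in a full design),
#'   adding `conversation_id` and the conversation `duration_ms` to the
#'   per-conversation target columns.
#' @export
design_targets <- function(design) {
  rows <- lapply(design$conversations, function(cv) {
    cbind(
      data.frame(conversation_id = cv$id, duration_ms = cv$duration_ms,
                 stringsAsFactors = FALSE),
      cv$targets
    )
  })
  do.call(rbind, rows)
}

#' @export
print.experiment_design <- function(x, ...) {
  tg <- design_targets(x)
  cat("Experiment design:", length(x$conversations), "conversations,",
      nrow(tg), "target events\n")
  cat("  durations:",
      paste0(round(range(vapply(x$conversations, `[[`, 0, "duration_ms")) / 1000, 1),
             collapse = "-"), "s\n")
  cat("  targets per condition:\n")
  print(table(condition = tg$condition, speaker = tg$prior_speaker))
  invisible(x)
}

#' Validate an experiment design against its structural constraints
#'
#' Checks every design invariant: conversation and utterance counts, the one
#' target per condition rule, half-open utterance intervals with exact 500 ms
#' gaps, 500 ms target silences, outcome rules (syntactically incomplete
#' targets always continue; half of the complete ones switch), transition
#' counts, conversation durations, speaker counterbalancing and the
#' presentation orders.
#'
#' @param design an `experiment_design` (or a structurally similar list).
#' @return A character vector of violation descriptions; empty when the design
#'   is valid. Each entry names the constraint and its location.
#' @examples
#' validate_design(generate_design(1)) # character(0)
#' @export
validate_design <- function(design) {
  v <- character(0)
  add <- function(msg) v <<- c(v, msg)

  convs <- design$conversations
  if (length(convs) != 8L) {
    add(sprintf("experiment: expected 8 conversations, found %d", length(convs)))
  }

  for (cv in convs) {
    id <- cv$id %||% "?"
    ut <- cv$utterances
    tg <- cv$targets

    if (nrow(tg) != 4L) {
      add(sprintf("%s: expected 4 target events (one per condition), found %d",
                  id, nrow(tg)))
    }
    if (!setequal(tg$condition, CONDITION_LEVELS) || anyDuplicated(tg$condition)) {
      add(sprintf("%s: targets must cover each condition exactly once", id))
    }

    if (any(ut$onset_ms >= ut$offset_ms)) {
      add(sprintf("%s: utterance with onset >= offset", id))
    }
    if (is.unsorted(ut$onset_ms, strictly = TRUE)) {
      add(sprintf("%s: utterances not strictly ordered by onset", id))
    }
    gaps <- ut$onset_ms[-1L] - ut$offset_ms[-nrow(ut)]
    if (any(gaps != SILENCE_MS)) {
      add(sprintf("%s: consecutive utterances must be separated by exactly %d ms (found %s)",
                  id, SILENCE_MS, paste(unique(gaps[gaps != SILENCE_MS]), collapse = ", ")))
    }
    if (any(xor(ut$is_target, !is.na(ut$condition)))) {
      add(sprintf("%s: condition must be present iff the utterance is a target", id))
    }
    if (sum(ut$is_target) != nrow(tg)) {
      add(sprintf("%s: %d target utterances but %d target events",
                  id, sum(ut$is_target), nrow(tg)))
    }

    sil_len <- tg$silence_offset_ms - tg$silence_onset_ms
    if (any(sil_len != SILENCE_MS)) {
      add(sprintf("%s: target silence must be exactly %d ms (found %s) [%s]",
                  id, SILENCE_MS,
                  paste(unique(sil_len[sil_len != SILENCE_MS]), collapse = ", "),
                  paste(tg$item_id[sil_len != SILENCE_MS], collapse = ", ")))
    }
    if (any(tg$responder == tg$prior_speaker)) {
      add(sprintf("%s: responder must differ from prior speaker [%s]",
                  id, paste(tg$item_id[tg$responder == tg$prior_speaker], collapse = ", ")))
    }

    flags <- condition_flags(tg$condition)
    bad_cont <- !flags$syntax_complete & tg$outcome != "CONTINUE"
    if (any(bad_cont)) {
      add(sprintf("%s: syntactically incomplete targets must be continuations (current speaker completes her turn) [%s]",
                  id, paste(tg$item_id[bad_cont], collapse = ", ")))
    }

    # target silences must coincide with the gap after the target utterance,
    # and the following utterance's speaker must encode the outcome
    for (k in seq_len(nrow(tg))) {
      sl <- which(ut$is_target & !is.na(ut$condition) & ut$condition == tg$condition[k])
      if (length(sl) != 1L) next
      if (ut$offset_ms[sl] != tg$silence_onset_ms[k]) {
        add(sprintf("%s: target silence of %s must start at the target utterance offset",
                    id, tg$item_id[k]))
      }
      if (ut$speaker[sl] != tg$prior_speaker[k]) {
        add(sprintf("%s: prior speaker of %s must be the target utterance's speaker",
                    id, tg$item_id[k]))
      }
      if (sl < nrow(ut)) {
        expected <- if (tg$outcome[k] == "SWITCH") tg$responder[k] else tg$prior_speaker[k]
        if (ut$speaker[sl + 1L] != expected) {
          add(sprintf("%s: utterance after %s must be spoken by the %s speaker to match outcome %s",
                      id, tg$item_id[k],
                      if (tg$outcome[k] == "SWITCH") "responding" else "same",
                      tg$outcome[k]))
        }
      } else {
        add(sprintf("%s: target %s must not be the final utterance", id, tg$item_id[k]))
      }
    }

    nt <- sum(ut$speaker[-1L] != ut$speaker[-nrow(ut)])
    if (nt < 5L || nt > 7L) {
      add(sprintf("%s: number of turn transitions must be 5-7, found %d", id, nt))
    }
    if (!is.null(cv$n_transitions) && cv$n_transitions != nt) {
      add(sprintf("%s: stored n_transitions (%d) disagrees with utterance sequence (%d)",
                  id, cv$n_transitions, nt))
    }
    dur <- cv$duration_ms
    if (dur != ut$offset_ms[nrow(ut)]) {
      add(sprintf("%s: duration_ms must equal the final utterance offset", id))
    }
    if (dur < 29000L || dur > 31000L) {
      add(sprintf("%s: conversation duration must be ~30 s (29-31 s), found %d ms", id, dur))
    }
  }

  tg <- tryCatch(design_targets(design), error = function(e) NULL)
  if (!is.null(tg)) {
    if (nrow(tg) != 32L) {
      add(sprintf("experiment: expected 32 target events in total, found %d", nrow(tg)))
    }
    per_cond <- table(factor(tg$condition, levels = CONDITION_LEVELS))
    if (any(per_cond != 8L)) {
      add("experiment: each condition must have exactly 8 targets")
    }
    per_spk <- table(factor(tg$prior_speaker, levels = c("LEFT", "RIGHT")))
    if (any(per_spk != 16L)) {
      add("experiment: targets must be equally divided between the two speakers (16 each)")
    }
    cs <- table(factor(tg$condition, levels = CONDITION_LEVELS),
                factor(tg$prior_speaker, levels = c("LEFT", "RIGHT")))
    if (any(cs != 4L)) {
      add("experiment: each condition must be spoken 4 times by each speaker")
    }
    for (lab in c("INCOMPLETE_PROSODY", "FULLY_COMPLETE")) {
      n_sw <- sum(tg$condition == lab & tg$outcome == "SWITCH")
      if (n_sw != 4L) {
        add(sprintf("experiment: %s targets must be followed by a speaker change exactly 4 of 8 times, found %d",
                    lab, n_sw))
      }
    }
  }

  po <- design$presentation_orders
  if (length(po) != 2L ||
      !all(vapply(po, function(o) setequal(o, seq_len(8L)), TRUE))) {
    add("experiment: presentation_orders must be two permutations of the 8 conversations")
  }

  v
}
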