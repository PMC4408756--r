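# Reading and writing experiment designs as YAML. One document per
# experiment: conversations -> utterances (speaker, onset, offset, target
# status, condition) plus the target-event table and presentation orders.
# Round-trip stable: load_design(save_design(d)) reproduces d exactly.

utterances_to_list <- function(ut) {
  lapply(seq_len(nrow(ut)), function(i) {
    list(
      index = as.integer(ut$index[i]),
      speaker = ut$speaker[i],
      onset_ms = as.integer(ut$onset_ms[i]),
      offset_ms = as.integer(ut$offset_ms[i]),
      is_target = as.logical(ut$is_target[i]),
      condition = if (is.na(ut$condition[i])) "NONE" else ut$condition[i]
    )
  })
}

targets_to_list <- function(tg) {
  lapply(seq_len(nrow(tg)), function(i) {
    list(
      item_id = tg$item_id[i],
      condition = tg$condition[i],
      prior_speaker = tg$prior_speaker[i],
      responder = tg$responder[i],
      silence_onset_ms = as.integer(tg$silence_onset_ms[i]),
      silence_offset_ms = as.integer(tg$silence_offset_ms[i]),
      outcome = tg$outcome[i]
    )
  })
}

#' Write an experiment design to a YAML file
#'
#' @param design an `experiment_design`, see [generate_design()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @seealso [load_design()]
#' @export
save_design <- function(design, path) {
  doc <- list(
    format = "turngaze-design",
    seed = as.integer(design$seed),
    presentation_orders = lapply(design$presentation_orders, as.integer),
    conversations = lapply(design$conversations, function(cv) {
      list(
        id = cv$id,
        duration_ms = as.integer(cv$duration_ms),
        n_transitions = as.integer(cv$n_transitions),
        utterances = utterances_to_list(cv$utterances),
        targets = targets_to_list(cv$targets)
      )
    })
  )
  yaml::write_yaml(doc, path)
  invisible(path)
}

field_or_stop <- function(x, name, where) {
  if (is.null(x[[name]])) {
    stop(sprintf("design file: missing field '%s' in %s", name, where),
         call. = FALSE)
  }
  x[[name]]
}

#' Read an experiment design from a YAML file
#'
#' Parses the structured-text design format written by [save_design()] and
#' validates it with [validate_design()]. A malformed file raises a parse
#' error naming the problem; a well-formed file that breaks a design
#' invariant raises a validation error listing every violation.
#'
#' @param path path to a design YAML file.
#' @return An `experiment_design`.
#' @export
load_design <- function(path) {
  check_that(file.exists(path), paste0("design file not found: ", path))
  doc <- tryCatch(
    yaml::read_yaml(path),
    error = function(e) {
      stop(sprintf("design file: cannot parse '%s': %s", path,
                   conditionMessage(e)), call. = FALSE)
    }
  )
  if (!identical(doc$format, "turngaze-design")) {
    stop(sprintf("design file: '%s' is not a turngaze design document", path),
         call. = FALSE)
  }
  convs <- field_or_stop(doc, "conversations", "document")
  conversations <- lapply(convs, function(cvl) {
    id <- field_or_stop(cvl, "id", "conversation")
    uts <- field_or_stop(cvl, "utterances", id)
    ut <- do.call(rbind, lapply(uts, function(u) {
      data.frame(
        index = as.integer(field_or_stop(u, "index", id)),
        speaker = field_or_stop(u, "speaker", id),
        onset_ms = as.integer(field_or_stop(u, "onset_ms", id)),
        offset_ms = as.integer(field_or_stop(u, "offset_ms", id)),
        is_target = as.logical(field_or_stop(u, "is_target", id)),
        condition = {
          cond <- field_or_stop(u, "condition", id)
          if (identical(cond, "NONE")) NA_character_ else cond
        },
        stringsAsFactors = FALSE
      )
    }))
    tgs <- field_or_stop(cvl, "targets", id)
    tg <- do.call(rbind, lapply(tgs, function(t) {
      data.frame(
        item_id = field_or_stop(t, "item_id", id),
        condition = field_or_stop(t, "condition", id),
        prior_speaker = field_or_stop(t, "prior_speaker", id),
        responder = field_or_stop(t, "responder", id),
        silence_onset_ms = as.integer(field_or_stop(t, "silence_onset_ms", id)),
        silence_offset_ms = as.integer(field_or_stop(t, "silence_offset_ms", id)),
        outcome = field_or_stop(t, "outcome", id),
        stringsAsFactors = FALSE
      )
    }))
    list(
      id = id,
      duration_ms = as.integer(field_or_stop(cvl, "duration_ms", id)),
      n_transitions = as.integer(field_or_stop(cvl, "n_transitions", id)),
      utterances = ut,
      targets = tg
    )
  })
  design <- structure(
    list(
      conversations = conversations,
      presentation_orders = lapply(field_or_stop(doc, "presentation_orders",
                                                 "document"), as.integer),
      seed = as.integer(doc$seed %||% NA_integer_)
    ),
    class = "experiment_design"
  )
  violations <- validate_design(design)
  if (length(violations) > 0L) {
    stop(paste0("design file '", path, "' violates design constraints:\n  - ",
                paste(violations, collapse = "\n  - ")), call. = FALSE)
  }
  design
}
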