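# Linear mixed-effects model suite on baseline-corrected switch scores.
# Two-level predictors are contrast-coded -1/+1, the intercept varies by
# subject and by item (crossed random intercepts), estimation is REML via
# lme4, and a fixed effect is called significant when |z| = |beta/SE| > 1.96
# (the Wald convention at alpha = 0.05).

CONTRAST_MAPS <- list(
  syntax = c(incomplete = -1, complete = 1),
  prosody = c(incomplete = -1, complete = 1),
  group = c(toddler = -1, adult = 1),
  speaker_change = c(no = -1, yes = 1, continue = -1, switch = 1),
  partial_condition = c(incomplete_syntax = -1, incomplete_prosody = 1)
)

#' Contrast-code a two-level predictor
#'
#' Maps factor levels to -1/+1 exactly as in the model tables: incomplete -1 /
#' complete +1 (syntax, prosody), toddler -1 / adult +1 (group), no -1 / yes
#' +1 (speaker change; `CONTINUE`/`SWITCH` outcomes are accepted as aliases),
#' incomplete syntax -1 / incomplete prosody +1 (the partial-conditions
#' contrast). Matching is case-insensitive.
#'
#' @param x character vector of levels.
#' @param factor which predictor the levels belong to.
#' @return Numeric vector over `{-1, 1}`.
#' @examples
#' code_contrasts(c("complete", "incomplete"), "syntax")
#' @export
code_contrasts <- function(x, factor = c("syntax", "prosody", "group",
                                         "speaker_change",
                                         "partial_condition")) {
  factor <- match.arg(factor)
  map <- CONTRAST_MAPS[[factor]]
  out <- unname(map[tolower(as.character(x))])
  if (anyNA(out) && !anyNA(x)) {
    stop(sprintf("unknown level(s) for %s contrast: %s", factor,
                 paste(unique(x[is.na(out)]), collapse = ", ")), call. = FALSE)
  }
  out
}

# Attach the -1/+1 model codes implied by condition/group/outcome.
add_contrast_codes <- function(obs) {
  flags <- condition_flags(obs$condition)
  obs$syn_code <- ifelse(flags$syntax_complete, 1, -1)
  obs$pros_code <- ifelse(flags$prosody_complete, 1, -1)
  obs$group_code <- code_contrasts(obs$group, "group")
  obs$change_code <- ifelse(flags$syntax_complete,
                            code_contrasts(obs$outcome, "speaker_change"),
                            NA_real_)
  obs
}

#' Fit one contrast-coded mixed model
#'
#' Fits `response ~ fixed + (1 | participant_id) + (1 | item_id)` by REML and
#' reports the coefficient table with `z = beta/SE` and the `|z| > 1.96`
#' significance flag. Degenerate data (for example a constant response) still
#' return a fit, flagged as singular, rather than an error.
#'
#' @param observations an observation table, see
#'   [compute_switch_observations()].
#' @param fixed right-hand-side formula text for the fixed effects, e.g.
#'   `"syn_code * pros_code * group_code"`.
#' @param response response column (default `"corrected"`).
#' @param label optional model label for printing.
#' @return An object of class `switch_model_fit`: a list with `coefficients`
#'   (term, beta, se, z, significant), `varcomp` (subject, item and residual
#'   variances), `n_obs`, `n_subjects`, `n_items`, `singular`, `degenerate`
#'   and the `formula`.
#' @export
fit_mixed_model <- function(observations, fixed, response = "corrected",
                            label = NULL) {
  check_that(nrow(observations) > 0L,
             paste0("model '", label %||% fixed, "': no observations"))
  n_subj <- length(unique(observations$participant_id))
  n_item <- length(unique(observations$item_id))
  check_that(n_subj >= 2L && n_item >= 2L,
             paste0("model '", label %||% fixed,
                    "': need at least 2 subjects and 2 items, have ",
                    n_subj, " and ", n_item))
  fml <- stats::as.formula(paste(
    response, "~", fixed, "+ (1 | participant_id) + (1 | item_id)"
  ))
  degenerate <- FALSE
  msg <- character(0)
  fit <- withCallingHandlers(
    tryCatch(
      lme4::lmer(fml, data = observations, REML = TRUE),
      error = function(e) {
        degenerate <<- TRUE
        msg <<- c(msg, conditionMessage(e))
        NULL
      }
    ),
    warning = function(w) {
      msg <<- c(msg, conditionMessage(w))
      invokeRestart("muffleWarning")
    },
    message = function(m) {
      msg <<- c(msg, trimws(conditionMessage(m)))
      invokeRestart("muffleMessage")
    }
  )

  extracted <- NULL
  if (!is.null(fit)) {
    # summary() itself can fail on fully degenerate fits (e.g. a constant
    # response gives a non-positive-definite covariance); treat that the
    # same as a failed fit
    extracted <- tryCatch(suppressWarnings({
      cf <- summary(fit)$coefficients
      if (anyNA(cf[, "Std. Error"])) stop("degenerate standard errors")
      vcd <- as.data.frame(lme4::VarCorr(fit))
      list(
        coefs = data.frame(
          term = rownames(cf), beta = cf[, "Estimate"],
          se = cf[, "Std. Error"], z = cf[, "t value"],
          stringsAsFactors = FALSE, row.names = NULL
        ),
        vc = data.frame(component = vcd$grp, variance = vcd$vcov,
                        stringsAsFactors = FALSE),
        singular = lme4::isSingular(fit)
      )
    }), error = function(e) {
      degenerate <<- TRUE
      msg <<- c(msg, conditionMessage(e))
      NULL
    })
  }

  if (is.null(extracted)) {
    # degenerate fallback: ordinary least squares on the fixed part only
    lm_fit <- stats::lm(stats::as.formula(paste(response, "~", fixed)),
                        data = observations)
    cf <- summary(lm_fit)$coefficients
    extracted <- list(
      coefs = data.frame(
        term = rownames(cf), beta = cf[, 1], se = cf[, 2],
        z = ifelse(cf[, 2] > 0, cf[, 1] / cf[, 2], NA_real_),
        stringsAsFactors = FALSE, row.names = NULL
      ),
      vc = data.frame(component = c("participant_id", "item_id", "Residual"),
                      variance = c(0, 0, stats::sigma(lm_fit)^2),
                      stringsAsFactors = FALSE),
      singular = TRUE
    )
  }
  coefs <- extracted$coefs
  vc <- extracted$vc
  singular <- extracted$singular
  coefs$significant <- !is.na(coefs$z) & abs(coefs$z) > 1.96
  structure(
    list(
      label = label %||% fixed,
      formula = fml,
      coefficients = coefs,
      varcomp = vc,
      n_obs = nrow(observations),
      n_subjects = n_subj,
      n_items = n_item,
      singular = singular,
      degenerate = degenerate,
      messages = msg
    ),
    class = "switch_model_fit"
  )
}

#' @export
print.switch_model_fit <- function(x, ...) {
  cat("Mixed model:", x$label, "\n")
  cat(sprintf("  %d observations; %d subjects; %d items%s\n", x$n_obs,
              x$n_subjects, x$n_items,
              if (x$singular) " (singular fit)" else ""))
  tab <- x$coefficients
  tab$beta <- signif(tab$beta, 3)
  tab$se <- signif(tab$se, 3)
  tab$z <- signif(tab$z, 3)
  tab$sig <- ifelse(tab$significant, "*", "")
  print(tab[, c("term", "beta", "se", "z", "sig")], row.names = FALSE)
  cat("  random-intercept variances:",
      paste(sprintf("%s=%.4g", x$varcomp$component, x$varcomp$variance),
            collapse = ", "), "\n")
  invisible(x)
}

#' Fit the full model suite
#'
#' Fits, in order: (a) the main factorial model `syntax x prosody x group` on
#' all targets; (b) the partial-conditions model (incomplete syntax -1 /
#' incomplete prosody +1, crossed with group) on the two partially complete
#' conditions; (c) the prosody x group model on syntactically complete
#' targets only; (d) the same subset adding the speaker-change contrast and
#' its interactions; (e, f) refits of the main model on the first two and
#' last two trials in presentation order.
#'
#' @param observations a complete observation table.
#' @param exclude_items item ids to drop before fitting (e.g. targets whose
#'   prosodic contour pre-tested as ambiguous).
#' @return A named list of `switch_model_fit`s
#'   (`main`, `partial_conditions`, `complete_syntax`, `speaker_change`,
#'   `first_two_trials`, `last_two_trials`), class `switch_model_suite`.
#' @export
run_model_suite <- function(observations, exclude_items = character(0)) {
  obs <- observations[!(observations$item_id %in% exclude_items), ,
                      drop = FALSE]
  check_that(nrow(obs) > 0L, "model suite: no observations after item exclusion")

  subset_or_stop <- function(keep, what) {
    out <- obs[keep, , drop = FALSE]
    check_that(nrow(out) > 0L,
               paste0("model suite: empty subset for the ", what, " model"))
    out
  }

  partial <- subset_or_stop(
    obs$condition %in% c("INCOMPLETE_SYNTAX", "INCOMPLETE_PROSODY"),
    "partial-conditions")
  partial$partial_code <- code_contrasts(partial$condition, "partial_condition")
  syn_complete <- subset_or_stop(obs$syn_code == 1, "complete-syntax")
  first_two <- subset_or_stop(obs$presentation_index <= 2L, "first-two-trials")
  last_two <- subset_or_stop(obs$presentation_index >= 7L, "last-two-trials")

  main_fixed <- "syn_code * pros_code * group_code"
  suite <- list(
    main = fit_mixed_model(obs, main_fixed, label = "main factorial"),
    partial_conditions = fit_mixed_model(
      partial, "partial_code * group_code", label = "partial conditions"),
    complete_syntax = fit_mixed_model(
      syn_complete, "pros_code * group_code",
      label = "syntactically complete targets"),
    speaker_change = fit_mixed_model(
      syn_complete, "pros_code * group_code * change_code",
      label = "speaker change (complete syntax)"),
    first_two_trials = fit_mixed_model(
      first_two, main_fixed, label = "first two trials"),
    last_two_trials = fit_mixed_model(
      last_two, main_fixed, label = "last two trials")
  )
  structure(suite, class = "switch_model_suite")
}

#' @export
print.switch_model_suite <- function(x, ...) {
  for (fit in x) {
    print(fit)
    cat("\n")
  }
  invisible(x)
}

#' Condition-level summary of switch scores
#'
#' Means and standard errors of the mean, per condition x group, for the
#' observed indicator, the chance baseline and the corrected score (the
#' structure of the actual-vs-baseline and corrected-by-group figures). By
#' default the SEM reflects between-participant variability: scores are first
#' averaged within participant x condition, then summarized across
#' participants. `by = "observation"` summarizes raw observations instead.
#'
#' @param observations an observation table.
#' @param by `"participant"` (default) or `"observation"`.
#' @return A data frame with one row per condition x group and columns
#'   `<measure>_mean` / `<measure>_sem` for `actual`, `baseline`, `corrected`.
#' @export
condition_summary <- function(observations,
                              by = c("participant", "observation")) {
  by <- match.arg(by)
  measures <- c("actual", "baseline", "corrected")
  sem <- function(x) if (length(x) > 1L) stats::sd(x) / sqrt(length(x)) else 0
  cells <- expand.grid(condition = CONDITION_LEVELS,
                       group = sort(unique(observations$group)),
                       stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(cells)), function(i) {
    sub <- observations[observations$condition == cells$condition[i] &
                          observations$group == cells$group[i], , drop = FALSE]
    row <- cells[i, , drop = FALSE]
    if (by == "participant") {
      row$n <- length(unique(sub$participant_id))
    } else {
      row$n <- nrow(sub)
    }
    for (m in measures) {
      vals <- if (by == "participant") {
        as.numeric(tapply(sub[[m]], sub$participant_id, mean))
      } else {
        sub[[m]]
      }
      row[[paste0(m, "_mean")]] <- mean(vals)
      row[[paste0(m, "_sem")]] <- sem(vals)
    }
    row
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
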