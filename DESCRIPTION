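Package: turngaze
Title: Anticipatory Gaze Switches at Conversational Turn Transitions
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for anticipatory gaze switches in screen-based
    eye-tracking studies of conversational turn taking. Provides a generator and
    validator for dyadic conversation stimulus designs with factorial
    lexicosyntactic and prosodic completeness conditions, readers for eye-tracker
    sample exports with per-eye validity handling, screen-attention exclusion
    rules, a three-criterion detector for anticipatory gaze switches around turn
    transitions, a shuffled-window Monte Carlo chance baseline with subtraction
    correction, a suite of contrast-coded linear mixed-effects models with
    crossed random intercepts for subject and item, and a synthetic gaze-data
    generator with ground-truth anticipation labels so the full pipeline can be
    exercised end to end without access to participant recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    lme4,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
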