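# Cohort selection and study-level classification.

#' Select the condition-specific, status-eligible study cohort
#'
#' A study is retained iff any configured keyword occurs case-insensitively
#' in its conditions, brief title, or official title, AND its overall status
#' is eligible. Selection is deterministic and idempotent; an empty input
#' yields an empty cohort.
#'
#' @param studies a `study_table`.
#' @param config a [cohort_config()].
#' @return the retained rows, a `study_table`.
#' @export
select_cohort <- function(studies, config) {
  stopifnot(inherits(config, "cohort_config"))
  if (nrow(studies) == 0L) return(studies)
  kw <- config$condition_keywords
  hit <- vapply(seq_len(nrow(studies)), function(i) {
    hay <- tolower(c(studies$conditions[[i]], studies$brief_title[i],
                     studies$official_title[i]))
    hay <- hay[!is.na(hay)]
    any(vapply(kw, function(k) any(grepl(k, hay, fixed = TRUE)), logical(1)))
  }, logical(1))
  keep <- hit & studies$overall_status %in% config$eligible_statuses
  out <- studies[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Collapse a registry phase value to a single numeric level
#'
#' Combined-phase records are promoted to their higher phase (a phase 2/3
#' trial counts as phase 3, a phase 1/2 trial as phase 2); early phase 1
#' groups with phase 1; not-applicable maps to level 0.
#'
#' @param phase character vector of [study_phases()] values.
#' @return integer vector in 0..4.
#' @export
#' @examples
#' effective_phase(c("phase_2_3", "phase_4", "na"))  # 3 4 0
effective_phase <- function(phase) {
  map <- c(na = 0L, early_phase_1 = 1L, phase_1 = 1L, phase_1_2 = 2L,
           phase_2 = 2L, phase_2_3 = 3L, phase_3 = 3L, phase_4 = 4L)
  out <- unname(map[phase])
  if (anyNA(out))
    abort(sprintf("unknown phase value(s): %s",
                  paste(unique(phase[is.na(out)]), collapse = ", ")),
          "trialpubs_validation_error")
  out
}

#' Flag vaccine trials by title keyword
#'
#' The registry has no structured vaccine intervention type; vaccine trials
#' are identified by a case-insensitive keyword match in the brief title.
#'
#' @inheritParams select_cohort
#' @return logical vector, one per study.
#' @export
flag_vaccine_trials <- function(studies, config) {
  grepl(config$vaccine_title_keyword, tolower(studies$brief_title), fixed = TRUE) &
    !is.na(studies$brief_title)
}

#' Classify when a study registered relative to its conduct
#'
#' Studies register at three points: `prior` to initiation (registration on
#' or before the start date), `during` conduct, or `after` completion
#' (registration strictly after the completion date, preferring the primary
#' completion date). Missing anchoring dates route to `undetermined`; no
#' interval arithmetic ever consumes a missing date.
#'
#' @param studies a `study_table`.
#' @return character vector: `prior`, `during`, `after`, `undetermined`.
#' @export
registration_timing <- function(studies) {
  n <- nrow(studies)
  out <- character(n)
  comp <- ifelse(is.na(studies$primary_completion_date),
                 studies$completion_date, studies$primary_completion_date)
  comp <- as.Date(comp, origin = "1970-01-01")
  for (i in seq_len(n)) {
    fp <- studies$first_posted_date[i]
    st <- studies$start_date[i]
    cp <- comp[i]
    out[i] <- if (is.na(fp)) "undetermined"
      else if (!is.na(st) && fp <= st) "prior"
      else if (!is.na(cp) && cp < fp) "after"
      else if (is.na(st)) "undetermined"
      else "during"
  }
  out
}

#' Categorize free-text termination reasons
#'
#' Applies the lexicon's lowercase-substring rules in fixed category order
#' (recruitment, safety, futility, external_results). A reason that matches
#' nothing is `other`; an absent reason is `unspecified`.
#'
#' @param why_stopped character vector (NA for absent).
#' @param lexicon see [termination_lexicon()].
#' @return character vector of categories.
#' @export
categorize_termination <- function(why_stopped, lexicon = termination_lexicon()) {
  vapply(why_stopped, function(ws) {
    if (is.na(ws) || !nzchar(trimws(ws))) return("unspecified")
    w <- tolower(ws)
    for (cat in c("recruitment", "safety", "futility", "external_results")) {
      pats <- lexicon[[cat]]
      if (length(pats) && any(vapply(pats, grepl, logical(1), x = w, fixed = TRUE)))
        return(cat)
    }
    "other"
  }, character(1), USE.NAMES = FALSE)
}

#' Derive all study-level classifications for a cohort
#'
#' @inheritParams select_cohort
#' @param cohort_ncts accessions retained by [select_cohort()]; defaults to
#'   all studies in the table.
#' @return data.frame: `nct_id`, `in_cohort`, `is_vaccine_trial`,
#'   `registration_timing`, `termination_category` (NA unless terminated),
#'   `effective_phase`.
#' @export
classify_studies <- function(studies, config, cohort_ncts = studies$nct_id) {
  tc <- rep(NA_character_, nrow(studies))
  term <- studies$overall_status == "terminated"
  tc[term] <- categorize_termination(studies$why_stopped[term], config$lexicon)
  data.frame(
    nct_id = studies$nct_id,
    in_cohort = studies$nct_id %in% cohort_ncts,
    is_vaccine_trial = flag_vaccine_trials(studies, config),
    registration_timing = registration_timing(studies),
    termination_category = tc,
    effective_phase = effective_phase(studies$phase),
    stringsAsFactors = FALSE
  )
}
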