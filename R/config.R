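# Run configuration: condition keywords, status eligibility, termination
# lexicon, intervention synonym map, scoring weights. Everything a site
# might retune lives here, not in code, and can be read from one YAML file.

#' Default condition keyword list for COVID-19 surveillance
#'
#' A representative keyword set for identifying COVID-19 studies by
#' case-insensitive substring match against conditions and titles. The list
#' is configuration, not code: pass your own to [cohort_config()] for any
#' other condition.
#'
#' @return lowercase character vector.
#' @export
covid_keywords <- function() {
  c("covid", "covid-19", "sars-cov-2", "2019-ncov", "sars-cov2",
    "novel coronavirus")
}

#' Default termination-reason lexicon
#'
#' Lowercase substring rules mapping free-text `why_stopped` registry fields
#' to termination categories. First matching category in the order
#' recruitment, safety, futility, external_results wins; a present but
#' unmatched reason maps to `other`, an absent one to `unspecified`.
#'
#' @return named list: category -> character vector of substrings.
#' @export
termination_lexicon <- function() {
  list(
    recruitment = c("recruit", "enroll", "accrual", "no participants",
                    "lack of participants", "low inclusion"),
    safety = c("safety", "adverse", "toxicity", "serious side effect",
               "harm"),
    futility = c("futility", "futile", "lack of efficacy", "no efficacy",
                 "ineffective", "efficacy not", "did not show efficacy"),
    external_results = c("other trial", "other studies", "external evidence",
                         "results from other", "published evidence",
                         "landscape", "no longer needed", "standard of care changed")
  )
}

#' Cohort selection configuration
#'
#' @param condition_keywords non-empty character vector of lowercase
#'   keywords; a study is on-condition when any keyword occurs
#'   case-insensitively in its conditions, brief title, or official title.
#' @param eligible_statuses non-empty subset of [study_statuses()].
#'   The default — recruiting, active (including enrolling by invitation),
#'   or ended (completed or terminated) — captures studies that are running
#'   or have run.
#' @param vaccine_title_keyword substring marking vaccine trials in the
#'   brief title.
#' @param focus_country country whose site presence feeds the attention
#'   score and shortlist.
#' @param lexicon termination-reason lexicon, see [termination_lexicon()].
#' @return object of class `cohort_config`.
#' @export
cohort_config <- function(condition_keywords = covid_keywords(),
                          eligible_statuses = c("recruiting",
                                                "active_not_recruiting",
                                                "enrolling_by_invitation",
                                                "completed", "terminated"),
                          vaccine_title_keyword = "vaccine",
                          focus_country = "United States",
                          lexicon = termination_lexicon()) {
  condition_keywords <- tolower(as.character(condition_keywords))
  if (length(condition_keywords) == 0L)
    abort("condition_keywords must be non-empty", "trialpubs_config_error")
  if (length(eligible_statuses) == 0L ||
      !all(eligible_statuses %in% study_statuses()))
    abort("eligible_statuses must be a non-empty subset of study_statuses()",
          "trialpubs_config_error")
  structure(list(condition_keywords = condition_keywords,
                 eligible_statuses = eligible_statuses,
                 vaccine_title_keyword = tolower(vaccine_title_keyword),
                 focus_country = focus_country,
                 lexicon = lexicon),
            class = "cohort_config")
}

#' Attention-score weights
#'
#' Parameters of the publication attention score (see [attention_score()]).
#' All weights are non-negative and the article-type weights must be
#' non-increasing from result to protocol to other, so that result articles
#' always outrank equally-situated protocols and editorials.
#'
#' @param type_weight named numeric: multiplier per article class.
#' @param us_bonus additive bonus for at least one focus-country site.
#' @param update_unit additive score per registry record update beyond the
#'   initial registration.
#' @param update_cap ceiling on the update term.
#' @param recency_scale e-folding time (days) of the recency term.
#' @param recency_weight weight of the recency term at age zero.
#' @param intervention_weight weight of the normalized intervention
#'   significance term.
#' @return object of class `attention_weights`.
#' @export
attention_weights <- function(type_weight = c(result = 1, protocol = 0.5,
                                              other = 0.25),
                              us_bonus = 0.5, update_unit = 0.01,
                              update_cap = 0.25, recency_scale = 180,
                              recency_weight = 0.25,
                              intervention_weight = 0.1) {
  w <- list(type_weight = type_weight, us_bonus = us_bonus,
            update_unit = update_unit, update_cap = update_cap,
            recency_scale = recency_scale, recency_weight = recency_weight,
            intervention_weight = intervention_weight)
  nums <- unlist(w)
  if (any(!is.finite(nums)) || any(nums < 0))
    abort("all attention weights must be finite and >= 0", "trialpubs_config_error")
  tw <- type_weight[c("result", "protocol", "other")]
  if (anyNA(tw) || is.unsorted(rev(tw)))
    abort("type_weight must satisfy result >= protocol >= other",
          "trialpubs_config_error")
  structure(w, class = "attention_weights")
}

#' Read a surveillance configuration file
#'
#' One YAML file holds the cohort configuration, attention weights,
#' shortlist threshold, project name, and intervention synonym map. Absent
#' keys fall back to package defaults.
#'
#' @param path YAML file path, or `NULL` for all defaults.
#' @return list with elements `cohort` ([cohort_config()]), `weights`
#'   ([attention_weights()]), `min_updates` (shortlist threshold),
#'   `project` (output file prefix), `synonyms` (named character vector
#'   raw -> canonical).
#' @export
read_surveillance_config <- function(path = NULL) {
  if (!is.null(path) && !file.exists(path))
    abort(sprintf("config file not found: %s", path), "trialpubs_config_error")
  raw <- if (is.null(path)) list() else tryCatch(
    yaml::read_yaml(path),
    error = function(e) abort(sprintf("cannot read config '%s': %s", path,
                                      conditionMessage(e)),
                              "trialpubs_config_error"))
  ch <- raw$cohort %||% list()
  lex <- if (is.null(ch$lexicon)) termination_lexicon()
         else lapply(ch$lexicon, as.character)
  cohort <- cohort_config(
    condition_keywords = ch$condition_keywords %||% covid_keywords(),
    eligible_statuses = ch$eligible_statuses %||%
      c("recruiting", "active_not_recruiting", "enrolling_by_invitation",
        "completed", "terminated"),
    vaccine_title_keyword = ch$vaccine_title_keyword %||% "vaccine",
    focus_country = ch$focus_country %||% "United States",
    lexicon = lex)
  wl <- raw$weights %||% list()
  weights <- attention_weights(
    type_weight = unlist(wl$type_weight) %||%
      c(result = 1, protocol = 0.5, other = 0.25),
    us_bonus = wl$us_bonus %||% 0.5,
    update_unit = wl$update_unit %||% 0.01,
    update_cap = wl$update_cap %||% 0.25,
    recency_scale = wl$recency_scale %||% 180,
    recency_weight = wl$recency_weight %||% 0.25,
    intervention_weight = wl$intervention_weight %||% 0.1)
  syn <- character()
  if (!is.null(raw$synonym_file)) {
    sf <- raw$synonym_file
    if (!is.null(path) && !file.exists(sf))
      sf <- file.path(dirname(path), raw$synonym_file)
    syn <- read_synonym_map(sf)
  } else if (!is.null(raw$synonyms)) {
    syn <- vapply(raw$synonyms, as.character, character(1))
  }
  list(cohort = cohort, weights = weights,
       min_updates = raw$min_updates %||% 2L,
       project = raw$project %||% "trialpubs",
       synonyms = syn)
}

#' Read an intervention synonym map
#'
#' Two-column CSV (`raw_string`, `canonical_string`); applied after textual
#' normalization, so entries should be in normalized (lowercase) form.
#'
#' @param path CSV file path.
#' @return named character vector raw -> canonical.
#' @export
read_synonym_map <- function(path) {
  if (!file.exists(path))
    abort(sprintf("synonym file not found: %s", path), "trialpubs_config_error")
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!all(c("raw_string", "canonical_string") %in% names(df)))
    abort("synonym map needs columns raw_string, canonical_string",
          "trialpubs_config_error")
  stats::setNames(df$canonical_string, df$raw_string)
}
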