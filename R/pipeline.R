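# End-to-end orchestration: cohort -> links -> scores -> ranked list ->
# shortlist -> summary -> outputs.

#' Run the full surveillance pipeline
#'
#' Selects the condition cohort, discovers and filters trial-article links,
#' aggregates intervention profiles, scores and ranks publications, builds
#' the prioritized shortlist and the aggregate summary, and (optionally)
#' writes the CSV/report outputs.
#'
#' @param studies a `study_table` (the full parsed corpus).
#' @param articles an `article_table`.
#' @param config list from [read_surveillance_config()] (or `NULL` for
#'   defaults).
#' @param as_of query date anchoring recency and completion comparisons.
#' @param out_dir optional output directory for [write_outputs()].
#' @param scope scope tag used in output file names.
#' @return list: `cohort`, `classifications`, `links`, `accounting`,
#'   `removed`, `profiles`, `ranked`, `shortlist`, `summary`, `files`.
#' @export
run_pipeline <- function(studies, articles, config = NULL,
                         as_of = Sys.Date(), out_dir = NULL, scope = "all") {
  config <- config %||% read_surveillance_config(NULL)
  cohort <- select_cohort(studies, config$cohort)
  cls <- classify_studies(studies, config$cohort, cohort$nct_id)
  link_set <- build_links(cohort, articles)
  interventional <- cohort[cohort$study_type == "interventional", , drop = FALSE]
  profiles <- intervention_profiles(interventional, link_set$links,
                                    config$synonyms)
  scored <- score_publications(link_set$links, cohort, profiles,
                               config$synonyms, config$weights, as_of,
                               config$cohort$focus_country)
  ranked <- rank_publications(scored)
  short <- shortlist(ranked, config$min_updates)
  summ <- surveillance_summary(cohort, link_set, config$cohort, as_of,
                               n_shortlist = nrow(short))
  files <- NULL
  if (!is.null(out_dir))
    files <- write_outputs(out_dir, config$project, cohort, ranked, profiles,
                           summ, removed = link_set$removed, scope = scope)
  list(cohort = cohort, classifications = cls, links = link_set$links,
       accounting = link_set$accounting, removed = link_set$removed,
       profiles = profiles, ranked = ranked, shortlist = short,
       summary = summ, files = files)
}
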