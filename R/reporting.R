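# Aggregate surveillance reporting: intervention tables, percentages,
# publication-timing analytics, result-deposition cross-tabs, and the CSV /
# markdown outputs of a run.

#' Printed percentage
#'
#' `100 * numerator / denominator`, rounded half-up to one decimal place —
#' the rounding used for every percentage the package prints.
#'
#' @param numerator,denominator counts; the denominator must be positive.
#' @return numeric, one decimal place.
#' @export
#' @examples
#' percentage(419, 2669)  # 15.7
percentage <- function(numerator, denominator) {
  if (any(denominator <= 0))
    abort("percentage() needs a positive denominator", "trialpubs_validation_error")
  round_half_up(100 * numerator / denominator, 1)
}

#' Ranked intervention table
#'
#' Orders intervention profiles by significance score descending, ties by
#' trial count descending then name ascending, and truncates to the top
#' `top_n` rows.
#'
#' @param profiles output of [intervention_profiles()].
#' @param top_n number of rows to keep (default 10).
#' @return the sorted, truncated profile data.frame.
#' @export
build_intervention_table <- function(profiles, top_n = 10L) {
  ord <- order(-profiles$significance_score, -profiles$trial_count,
               profiles$intervention)
  out <- profiles[ord, , drop = FALSE]
  out <- utils::head(out, top_n)
  rownames(out) <- NULL
  out
}

#' Publication lag statistics
#'
#' Lag from trial start to article publication, in days, for non-protocol
#' links. The trial start date is the anchor because registry completion
#' dates are often anticipated and in the future. Links whose publication
#' or start date is unresolved are excluded from the mean and counted.
#'
#' @param links master link data.frame with `article_class` and
#'   `publication_date`.
#' @param studies the cohort `study_table`.
#' @return list: `mean_days`, `n` (links in the mean), `n_undatable`,
#'   `lags` (per-link data.frame).
#' @export
publication_lag_stats <- function(links, studies) {
  nonprot <- links[!(links$article_class %in% "protocol"), , drop = FALSE]
  start <- studies$start_date[match(nonprot$nct_id, studies$nct_id)]
  lag <- as.numeric(nonprot$publication_date - start)
  ok <- !is.na(lag)
  list(mean_days = if (any(ok)) mean(lag[ok]) else NA_real_,
       n = sum(ok), n_undatable = sum(!ok),
       lags = data.frame(nct_id = nonprot$nct_id, pmid = nonprot$pmid,
                         lag_days = lag, stringsAsFactors = FALSE))
}

#' Result articles published before formal trial completion
#'
#' Counts result-class links whose study has no completion date on or
#' before `as_of` — either no completion date at all or one still in the
#' future — i.e. articles that appeared while the trial was not formally
#' complete.
#'
#' @param links master link data.frame.
#' @param studies the cohort `study_table`.
#' @param as_of the query date.
#' @return list: `n_links`, `n_trials`, `links` (the qualifying subset).
#' @export
pre_completion_publications <- function(links, studies, as_of = Sys.Date()) {
  res <- links[links$article_class %in% "result", , drop = FALSE]
  idx <- match(res$nct_id, studies$nct_id)
  comp <- ifelse(is.na(studies$primary_completion_date[idx]),
                 studies$completion_date[idx],
                 studies$primary_completion_date[idx])
  comp <- as.Date(comp, origin = "1970-01-01")
  not_complete <- is.na(comp) | comp > as_of
  out <- res[not_complete, , drop = FALSE]
  rownames(out) <- NULL
  list(n_links = nrow(out), n_trials = length(unique(out$nct_id)), links = out)
}

#' Result deposition vs. article publication cross-tab
#'
#' Partitions the cohort into four mutually exclusive cells by whether a
#' study deposited structured summary results in the registry and whether
#' it has at least one linked article. Cells always sum to the cohort size.
#'
#' @param studies the cohort `study_table`.
#' @param links master link data.frame.
#' @return named integer vector: `deposit_only`, `deposit_and_article`,
#'   `article_only`, `neither`.
#' @export
deposit_crosstab <- function(studies, links) {
  has_article <- studies$nct_id %in% links$nct_id
  dep <- studies$has_deposited_results
  out <- c(deposit_only = sum(dep & !has_article),
           deposit_and_article = sum(dep & has_article),
           article_only = sum(!dep & has_article),
           neither = sum(!dep & !has_article))
  stopifnot(sum(out) == nrow(studies))
  out
}

#' Abstract-review time saved by shortlisting
#'
#' Hours saved reviewing the shortlist instead of the full ranked list at a
#' fixed reading rate per abstract.
#'
#' @param n_full size of the full list.
#' @param n_short size of the shortlist (<= `n_full`).
#' @param minutes_per_abstract reading time per abstract (default 2).
#' @return hours, rounded half-up to one decimal.
#' @export
#' @examples
#' review_time_saved(760, 58)  # 23.4
review_time_saved <- function(n_full, n_short, minutes_per_abstract = 2) {
  if (n_short > n_full)
    abort("shortlist larger than full list", "trialpubs_validation_error")
  round_half_up((n_full - n_short) * minutes_per_abstract / 60, 1)
}

#' Aggregate surveillance summary for a cohort
#'
#' The study-level and link-level counts a surveillance report prints:
#' studies by type, trials with any/multiple linked articles, link-route
#' accounting, result-deposition cross-tab, registration-timing breakdown,
#' mean publication lag, pre-completion publications, zero-information
#' studies (no links and a never-updated record), and the review-time-saved
#' estimate.
#'
#' @param studies the cohort `study_table`.
#' @param link_set output of [build_links()].
#' @param config a [cohort_config()].
#' @param as_of the query date.
#' @param n_shortlist size of the prioritized shortlist, if computed.
#' @param minutes_per_abstract see [review_time_saved()].
#' @return list of class `surveillance_summary`.
#' @export
surveillance_summary <- function(studies, link_set, config = cohort_config(),
                                 as_of = Sys.Date(), n_shortlist = NA_integer_,
                                 minutes_per_abstract = 2) {
  links <- link_set$links
  acc <- link_set$accounting
  pubs_per_study <- table(links$nct_id)
  n_any <- length(pubs_per_study)
  n_multi <- sum(pubs_per_study >= 2)
  timing <- registration_timing(studies)
  lag <- publication_lag_stats(links, studies)
  prec <- pre_completion_publications(links, studies, as_of)
  dep <- deposit_crosstab(studies, links)
  zero_info <- sum(!(studies$nct_id %in% links$nct_id) &
                     studies$version_count == 1L)
  n <- nrow(studies)
  structure(list(
    as_of = as_of,
    n_studies = n,
    n_by_type = table(factor(studies$study_type, levels = study_types())),
    n_with_any_result_article = n_any,
    pct_with_any_result_article = if (n > 0) percentage(n_any, n) else NA_real_,
    n_with_multiple_articles = n_multi,
    n_vaccine_trials = sum(flag_vaccine_trials(studies, config)),
    accounting = acc,
    n_deposited_results = sum(studies$has_deposited_results),
    n_deposit_only = unname(dep["deposit_only"]),
    n_deposit_and_article = unname(dep["deposit_and_article"]),
    deposit_crosstab = dep,
    registration_timing = table(factor(timing, levels = c("prior", "during",
                                                          "after", "undetermined"))),
    mean_publication_lag_days = lag$mean_days,
    n_lag_links = lag$n,
    n_undatable_links = lag$n_undatable,
    n_published_before_completion = prec$n_links,
    n_trials_published_before_completion = prec$n_trials,
    n_zero_info_studies = zero_info,
    n_shortlist = n_shortlist,
    review_hours_saved = if (!is.na(n_shortlist))
      review_time_saved(acc$n_combinations, n_shortlist, minutes_per_abstract)
    else NA_real_
  ), class = "surveillance_summary")
}

#' @export
print.surveillance_summary <- function(x, ...) {
  cat(format_summary_lines(x), sep = "\n")
  invisible(x)
}

format_summary_lines <- function(x) {
  acc <- x$accounting
  c(sprintf("Surveillance summary (as of %s)", format(x$as_of)),
    sprintf("  studies: %d (%s)", x$n_studies,
            paste(sprintf("%d %s", as.integer(x$n_by_type), names(x$n_by_type)),
                  collapse = ", ")),
    sprintf("  with >=1 linked article: %d (%.1f%%); with multiple: %d",
            x$n_with_any_result_article, x$pct_with_any_result_article,
            x$n_with_multiple_articles),
    sprintf("  link combinations: %d (abstract %d, registry %d, both %d); distinct pairs %d; distinct articles %d",
            acc$n_combinations, acc$n_abstract, acc$n_registry, acc$n_both,
            acc$n_distinct_pairs, acc$n_distinct_articles),
    sprintf("  registry references removed as misclassified: %d",
            acc$n_removed_misclassified),
    sprintf("  deposition: %d deposited (%d deposit-only, %d deposit+article)",
            x$n_deposited_results, x$n_deposit_only, x$n_deposit_and_article),
    sprintf("  registration timing: %s",
            paste(sprintf("%s %d", names(x$registration_timing),
                          as.integer(x$registration_timing)), collapse = ", ")),
    sprintf("  mean publication lag: %s days over %d non-protocol links (%d undatable)",
            ifelse(is.na(x$mean_publication_lag_days), "NA",
                   sprintf("%.1f", x$mean_publication_lag_days)),
            x$n_lag_links, x$n_undatable_links),
    sprintf("  result articles before formal completion: %d (from %d trials)",
            x$n_published_before_completion, x$n_trials_published_before_completion),
    sprintf("  zero-information studies (no links, never updated): %d",
            x$n_zero_info_studies),
    if (!is.na(x$n_shortlist))
      sprintf("  shortlist: %d of %d; est. review time saved: %.1f h",
              x$n_shortlist, acc$n_combinations, x$review_hours_saved))
}

#' Write the CSV and report outputs of a surveillance run
#'
#' Emits RFC 4180 CSVs (UTF-8, header row, ISO 8601 dates) under the
#' project prefix: `<project>_trials_<scope>.csv`,
#' `<project>_publication_list_<scope>.csv`,
#' `<project>_intervention-phase_cnts_<scope>.csv`,
#' `<project>_removed_links.csv`, `<project>_Master.csv`, and a
#' human-readable `<project>_report.md`.
#'
#' @param out_dir output directory (created if needed).
#' @param project file-name prefix.
#' @param studies cohort `study_table`.
#' @param ranked ranked, scored link list.
#' @param profiles intervention profiles.
#' @param summary a [surveillance_summary()].
#' @param removed audit list of removed misclassified links.
#' @param scope scope tag for file names: `all`, `int`, `obs`, or `reg`.
#' @return character vector of files written, invisibly.
#' @export
write_outputs <- function(out_dir, project, studies, ranked, profiles,
                          summary, removed = NULL, scope = "all") {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  f <- function(stem) file.path(out_dir, sprintf("%s_%s.csv", project, stem))
  files <- character()
  flat <- as.data.frame(studies)[, c("nct_id", "brief_title", "study_type",
                                     "overall_status", "phase", "version_count",
                                     "lead_sponsor", "has_deposited_results")]
  flat$start_date <- format(studies$start_date, "%Y-%m-%d")
  flat$first_posted_date <- format(studies$first_posted_date, "%Y-%m-%d")
  utils::write.csv(flat, files[length(files) + 1] <- f(paste0("trials_", scope)),
                   row.names = FALSE, na = "")
  rk <- ranked
  rk$publication_date <- format(rk$publication_date, "%Y-%m-%d")
  utils::write.csv(rk, files[length(files) + 1] <- f(paste0("publication_list_", scope)),
                   row.names = FALSE, na = "")
  utils::write.csv(profiles,
                   files[length(files) + 1] <- f(paste0("intervention-phase_cnts_", scope)),
                   row.names = FALSE, na = "")
  utils::write.csv(rk, files[length(files) + 1] <- f("Master"),
                   row.names = FALSE, na = "")
  if (!is.null(removed)) {
    rm_ <- removed
    rm_$publication_date <- format(rm_$publication_date, "%Y-%m-%d")
    rm_$trial_start_date <- format(rm_$trial_start_date, "%Y-%m-%d")
    utils::write.csv(rm_, files[length(files) + 1] <- f("removed_links"),
                     row.names = FALSE, na = "")
  }
  report <- file.path(out_dir, sprintf("%s_report.md", project))
  top <- utils::head(ranked, 10)
  lines <- c(
    sprintf("# %s surveillance report", project), "",
    format_summary_lines(summary), "",
    "## Top interventions by significance score", "",
    paste(utils::capture.output(print(build_intervention_table(profiles))),
          collapse = "\n"), "",
    "## Top publications by attention score", "",
    paste(utils::capture.output(
      print(top[, intersect(c("rank", "pmid", "nct_id", "article_class",
                              "attention_score"), names(top))])),
      collapse = "\n"))
  writeLines(lines, report)
  files <- c(files, report)
  invisible(files)
}
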