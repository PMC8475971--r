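# Domain model: study and article tables.
#
# A corpus is held as two plain data.frames with list-columns, one row per
# registry study and one per bibliographic article. Multi-valued fields
# (interventions, references, secondary identifiers, ...) are list-columns so
# the whole corpus stays a single rectangular object that base R subsetting,
# merge() and split() handle directly.

#' Controlled vocabularies for registry study records
#'
#' @return character vector of allowed values.
#' @export
study_statuses <- function() {
  c("recruiting", "active_not_recruiting", "enrolling_by_invitation",
    "completed", "terminated", "suspended", "withdrawn",
    "not_yet_recruiting", "unknown")
}

#' @rdname study_statuses
#' @export
study_phases <- function() {
  c("na", "early_phase_1", "phase_1", "phase_1_2", "phase_2", "phase_2_3",
    "phase_3", "phase_4")
}

#' @rdname study_statuses
#' @export
study_types <- function() {
  c("interventional", "observational", "patient_registry")
}

.nct_regex <- "^NCT\\d{8}$"

#' Construct a single registry study record
#'
#' Builds one row of a study table. Optional fields left `NULL` become
#' explicit missing markers (`NA` / empty vectors); they are never silently
#' defaulted to plausible values. Dates may be given as strings in any
#' partial-date format understood by [resolve_partial_date()].
#'
#' @param nct_id registry accession (`NCT` + 8 digits).
#' @param brief_title short study title.
#' @param study_type one of [study_types()].
#' @param overall_status one of [study_statuses()].
#' @param phase one of [study_phases()]; default `"na"`.
#' @param official_title optional full title.
#' @param start_date,primary_completion_date,completion_date,first_posted_date,last_update_date
#'   optional partial-date strings.
#' @param version_count number of stored record versions including the
#'   initial registration (>= 1).
#' @param interventions data.frame with columns `name`, `type`, or `NULL`.
#' @param conditions character vector of condition terms.
#' @param lead_sponsor,collaborator_sponsors sponsor names.
#' @param site_countries character vector of site country names.
#' @param references data.frame with columns `pmid`, `type` (one of
#'   `result_reference`, `background`, `derived`), or `NULL`.
#' @param has_deposited_results logical: structured summary results deposited
#'   in the registry.
#' @param why_stopped optional free-text termination reason.
#' @return one-row data.frame of class `study_table`.
#' @export
study_record <- function(nct_id, brief_title, study_type, overall_status,
                         phase = "na", official_title = NULL,
                         start_date = NULL, primary_completion_date = NULL,
                         completion_date = NULL, first_posted_date = NULL,
                         last_update_date = NULL, version_count = 1L,
                         interventions = NULL, conditions = character(),
                         lead_sponsor = NA_character_,
                         collaborator_sponsors = character(),
                         site_countries = character(), references = NULL,
                         has_deposited_results = FALSE, why_stopped = NULL) {
  pd <- function(x) resolve_partial_date(chr1(x %||% NA_character_))
  sd <- pd(start_date); pcd <- pd(primary_completion_date)
  cd <- pd(completion_date); fp <- pd(first_posted_date); lu <- pd(last_update_date)
  iv <- interventions %||% data.frame(name = character(), type = character(),
                                      stringsAsFactors = FALSE)
  rf <- references %||% data.frame(pmid = character(), type = character(),
                                   stringsAsFactors = FALSE)
  rf$pmid <- as.character(rf$pmid)
  out <- data.frame(
    nct_id = as.character(nct_id),
    brief_title = as.character(brief_title),
    official_title = chr1(official_title %||% NA_character_),
    study_type = as.character(study_type),
    overall_status = as.character(overall_status),
    phase = as.character(phase),
    start_date = sd$date, start_date_precision = sd$precision,
    primary_completion_date = pcd$date,
    primary_completion_date_precision = pcd$precision,
    completion_date = cd$date, completion_date_precision = cd$precision,
    first_posted_date = fp$date, first_posted_date_precision = fp$precision,
    last_update_date = lu$date, last_update_date_precision = lu$precision,
    version_count = as.integer(version_count),
    lead_sponsor = chr1(lead_sponsor),
    why_stopped = chr1(why_stopped %||% NA_character_),
    has_deposited_results = isTRUE(has_deposited_results),
    stringsAsFactors = FALSE
  )
  out$interventions <- list(iv)
  out$conditions <- list(as.character(conditions))
  out$collaborator_sponsors <- list(as.character(collaborator_sponsors))
  out$site_countries <- list(as.character(site_countries))
  out$references <- list(rf)
  class(out) <- c("study_table", "data.frame")
  out
}

#' Bind study records into a study table
#'
#' @param records list of one-row study tables (from [study_record()] or a
#'   parser), or a single study table.
#' @param era_floor earliest admissible day-precision registration date;
#'   registration dates before this fail validation.
#' @return data.frame of class `study_table`, validated.
#' @export
study_table <- function(records, era_floor = as.Date("1999-01-01")) {
  if (is.data.frame(records)) records <- list(records)
  out <- do.call(rbind, records)
  if (is.null(out)) out <- study_record("NCT00000000", "", "interventional", "unknown")[0, ]
  class(out) <- c("study_table", "data.frame")
  rownames(out) <- NULL
  validate_study_table(out, era_floor = era_floor)
}

#' @rdname study_table
#' @param studies a study table to validate.
#' @export
validate_study_table <- function(studies, era_floor = as.Date("1999-01-01")) {
  bad <- !grepl(.nct_regex, studies$nct_id)
  if (any(bad))
    abort(sprintf("invalid NCT accession(s): %s",
                  paste(studies$nct_id[bad], collapse = ", ")),
          "trialpubs_validation_error")
  if (anyDuplicated(studies$nct_id))
    abort("duplicate NCT accessions in study table", "trialpubs_validation_error")
  if (!all(studies$study_type %in% study_types()))
    abort("unknown study_type value", "trialpubs_validation_error")
  if (!all(studies$overall_status %in% study_statuses()))
    abort("unknown overall_status value", "trialpubs_validation_error")
  if (!all(studies$phase %in% study_phases()))
    abort("unknown phase value", "trialpubs_validation_error")
  if (any(studies$version_count < 1L))
    abort("version_count must be >= 1", "trialpubs_validation_error")
  early <- studies$first_posted_date_precision == "day" &
    !is.na(studies$first_posted_date) & studies$first_posted_date < era_floor
  if (any(early))
    abort(sprintf("registration date before era floor %s for %s",
                  format(era_floor), paste(studies$nct_id[early], collapse = ", ")),
          "trialpubs_validation_error")
  studies
}

#' Construct a single bibliographic article record
#'
#' @param pmid PubMed identifier (numeric string).
#' @param title article title.
#' @param journal journal title.
#' @param publication_date partial-date string or `NULL`.
#' @param publication_types character vector of publication-type vocabulary
#'   strings (preserved verbatim; unknown strings are classified downstream
#'   as "other", never dropped).
#' @param secondary_ids data.frame with columns `databank`, `accession`
#'   (the DataBank list holding cited trial accessions), or `NULL`.
#' @param mesh_terms character vector of MeSH descriptor names.
#' @return one-row data.frame of class `article_table`.
#' @export
article_record <- function(pmid, title = NA_character_, journal = NA_character_,
                           publication_date = NULL,
                           publication_types = character(),
                           secondary_ids = NULL, mesh_terms = character()) {
  pd <- resolve_partial_date(chr1(publication_date %||% NA_character_))
  sid <- secondary_ids %||% data.frame(databank = character(),
                                       accession = character(),
                                       stringsAsFactors = FALSE)
  out <- data.frame(
    pmid = as.character(pmid),
    title = chr1(title),
    journal = chr1(journal),
    publication_date = pd$date,
    publication_date_precision = pd$precision,
    stringsAsFactors = FALSE
  )
  out$publication_types <- list(as.character(publication_types))
  out$secondary_ids <- list(sid)
  out$mesh_terms <- list(as.character(mesh_terms))
  class(out) <- c("article_table", "data.frame")
  out
}

#' Bind article records into an article table
#'
#' @param records list of one-row article tables, or a single article table.
#' @return data.frame of class `article_table`, validated.
#' @export
article_table <- function(records) {
  if (is.data.frame(records)) records <- list(records)
  out <- do.call(rbind, records)
  if (is.null(out)) out <- article_record("0")[0, ]
  class(out) <- c("article_table", "data.frame")
  rownames(out) <- NULL
  validate_article_table(out)
}

#' @rdname article_table
#' @param articles an article table to validate.
#' @export
validate_article_table <- function(articles) {
  if (any(is.na(articles$pmid) | !grepl("^\\d+$", articles$pmid)))
    abort("every article needs a numeric PMID", "trialpubs_validation_error")
  if (anyDuplicated(articles$pmid))
    abort("duplicate PMIDs in article table", "trialpubs_validation_error")
  for (i in seq_len(nrow(articles))) {
    sid <- articles$secondary_ids[[i]]
    ctg <- sid$accession[sid$databank == "ClinicalTrials.gov"]
    if (length(ctg) && !all(grepl(.nct_regex, ctg)))
      abort(sprintf("PMID %s: ClinicalTrials.gov secondary id not an NCT accession",
                    articles$pmid[i]), "trialpubs_validation_error")
  }
  articles
}

#' @export
print.study_table <- function(x, ...) {
  cat(sprintf("<study_table> %d studies (%s)\n", nrow(x),
              paste(sprintf("%d %s", table(x$study_type),
                            names(table(x$study_type))), collapse = ", ")))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, c("nct_id", "brief_title", "study_type",
                                           "overall_status", "phase")], 10))
  invisible(x)
}

#' @export
print.article_table <- function(x, ...) {
  cat(sprintf("<article_table> %d articles\n", nrow(x)))
  if (nrow(x))
    print(utils::head(as.data.frame(x)[, c("pmid", "title", "publication_date")], 10))
  invisible(x)
}
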