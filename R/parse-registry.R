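# Registry study-record parsing: ClinicalTrials.gov API v2 JSON and the
# legacy public-XML dialect. Both map onto the same study_table schema; the
# synthetic-corpus serializers in serialize.R are the inverse maps, and the
# round-trip property is tested corpus-wide.

.status_from_api <- c(
  RECRUITING = "recruiting", ACTIVE_NOT_RECRUITING = "active_not_recruiting",
  ENROLLING_BY_INVITATION = "enrolling_by_invitation", COMPLETED = "completed",
  TERMINATED = "terminated", SUSPENDED = "suspended", WITHDRAWN = "withdrawn",
  NOT_YET_RECRUITING = "not_yet_recruiting", UNKNOWN = "unknown"
)

.status_from_legacy <- c(
  "Recruiting" = "recruiting", "Active, not recruiting" = "active_not_recruiting",
  "Enrolling by invitation" = "enrolling_by_invitation", "Completed" = "completed",
  "Terminated" = "terminated", "Suspended" = "suspended", "Withdrawn" = "withdrawn",
  "Not yet recruiting" = "not_yet_recruiting", "Unknown status" = "unknown"
)

.phase_from_api <- c(
  NA_ = "na", EARLY_PHASE1 = "early_phase_1", PHASE1 = "phase_1",
  PHASE2 = "phase_2", PHASE3 = "phase_3", PHASE4 = "phase_4"
)

.phase_from_legacy <- c(
  "N/A" = "na", "Early Phase 1" = "early_phase_1", "Phase 1" = "phase_1",
  "Phase 1/Phase 2" = "phase_1_2", "Phase 2" = "phase_2",
  "Phase 2/Phase 3" = "phase_2_3", "Phase 3" = "phase_3", "Phase 4" = "phase_4"
)

.reftype_from_api <- c(RESULT = "result_reference", BACKGROUND = "background",
                       DERIVED = "derived")

.map_enum <- function(x, map, what, default = NULL) {
  if (is.null(x) || is.na(x) || !nzchar(x)) {
    if (!is.null(default)) return(default)
    abort(sprintf("missing %s", what), "trialpubs_parse_error")
  }
  out <- unname(map[x])
  if (is.na(out))
    abort(sprintf("unrecognized %s value: '%s'", what, x), "trialpubs_parse_error")
  out
}

#' Parse one registry study record
#'
#' Maps a single ClinicalTrials.gov study record, in either supported
#' dialect, onto the study-table schema. Every populated field is mapped;
#' absent optional fields become explicit missing markers, and
#' month-precision dates keep their precision flag.
#'
#' @param raw_record for `dialect = "api_v2_json"`: a JSON string or an
#'   already-decoded list; for `dialect = "legacy_xml"`: an XML string or an
#'   `xml2` node for one `<clinical_study>` element.
#' @param dialect `"api_v2_json"` or `"legacy_xml"`.
#' @return one-row `study_table`.
#' @seealso [read_study_records()] for whole files, [write_study_records()]
#'   for the inverse.
#' @export
parse_study_record <- function(raw_record, dialect = c("api_v2_json", "legacy_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "api_v2_json") parse_study_api_json(raw_record)
  else parse_study_legacy_xml(raw_record)
}

parse_study_api_json <- function(raw) {
  if (is.character(raw)) raw <- jsonlite::fromJSON(raw, simplifyVector = FALSE)
  ps <- raw$protocolSection
  if (is.null(ps)) abort("malformed study record: no protocolSection", "trialpubs_parse_error")
  idm <- ps$identificationModule
  nct <- idm$nctId
  if (is.null(nct) || !nzchar(nct))
    abort("study record rejected: missing NCT ID at protocolSection.identificationModule.nctId",
          "trialpubs_parse_error")
  st <- ps$statusModule %||% list()
  dm <- ps$designModule %||% list()
  study_type <- switch(toupper(dm$studyType %||% ""),
    INTERVENTIONAL = "interventional",
    OBSERVATIONAL = if (isTRUE(dm$patientRegistry)) "patient_registry" else "observational",
    abort(sprintf("unrecognized studyType in %s", nct), "trialpubs_parse_error")
  )
  phases <- vapply(dm$phases %||% list(), function(p) {
    .map_enum(sub("^NA$", "NA_", p), .phase_from_api, "phase")
  }, character(1))
  phase <- combine_phases(phases)
  ivs <- ps$armsInterventionsModule$interventions %||% list()
  refs <- ps$referencesModule$references %||% list()
  refs <- Filter(function(r) !is.null(r$pmid) && nzchar(r$pmid), refs)
  locs <- ps$contactsLocationsModule$locations %||% list()
  spon <- ps$sponsorCollaboratorsModule %||% list()
  dstr <- function(x) x$date %||% NA_character_
  study_record(
    nct_id = nct,
    brief_title = idm$briefTitle %||% NA_character_,
    official_title = idm$officialTitle,
    study_type = study_type,
    overall_status = .map_enum(st$overallStatus, .status_from_api,
                               "overallStatus", default = "unknown"),
    phase = phase,
    start_date = dstr(st$startDateStruct),
    primary_completion_date = dstr(st$primaryCompletionDateStruct),
    completion_date = dstr(st$completionDateStruct),
    first_posted_date = dstr(st$studyFirstPostDateStruct),
    last_update_date = dstr(st$lastUpdatePostDateStruct),
    version_count = raw$versionCount %||% 1L,
    interventions = data.frame(
      name = vapply(ivs, function(v) v$name %||% NA_character_, character(1)),
      type = vapply(ivs, function(v) tolower(v$type %||% "other"), character(1)),
      stringsAsFactors = FALSE),
    conditions = unlist(ps$conditionsModule$conditions %||% list()) %||% character(),
    lead_sponsor = spon$leadSponsor$name %||% NA_character_,
    collaborator_sponsors = vapply(spon$collaborators %||% list(),
                                   function(x) x$name %||% NA_character_, character(1)),
    site_countries = unique(vapply(locs, function(x) x$country %||% NA_character_,
                                   character(1))),
    references = data.frame(
      pmid = vapply(refs, function(r) as.character(r$pmid), character(1)),
      type = vapply(refs, function(r) .map_enum(r$type, .reftype_from_api,
                                                "reference type"), character(1)),
      stringsAsFactors = FALSE),
    has_deposited_results = isTRUE(raw$hasResults),
    why_stopped = st$whyStopped
  )
}

# a record listing two consecutive phases is the combined-phase enum value
combine_phases <- function(phases) {
  phases <- sort(unique(phases[!is.na(phases)]))
  if (length(phases) == 0L) return("na")
  if (length(phases) == 1L) return(phases)
  key <- paste(sort(phases), collapse = "+")
  out <- c("phase_1+phase_2" = "phase_1_2", "phase_2+phase_3" = "phase_2_3")[key]
  if (is.na(out))
    abort(sprintf("unsupported phase combination: %s", key), "trialpubs_parse_error")
  unname(out)
}

parse_study_legacy_xml <- function(raw) {
  node <- if (inherits(raw, "xml_node")) raw else xml2::xml_find_first(
    xml2::read_xml(raw), "//clinical_study")
  if (inherits(node, "xml_missing") || is.na(xml2::xml_name(node)) ||
      xml2::xml_name(node) != "clinical_study")
    abort("malformed study record: no <clinical_study> element", "trialpubs_parse_error")
  txt <- function(xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_character_ else trimws(xml2::xml_text(n))
  }
  txts <- function(xp) trimws(xml2::xml_text(xml2::xml_find_all(node, xp)))
  nct <- txt("id_info/nct_id")
  if (is.na(nct) || !nzchar(nct))
    abort("study record rejected: missing <id_info><nct_id>", "trialpubs_parse_error")
  type_raw <- txt("study_type")
  study_type <- switch(type_raw %||% "",
    "Interventional" = "interventional",
    "Observational" = "observational",
    "Observational [Patient Registry]" = "patient_registry",
    abort(sprintf("unrecognized study_type '%s' in %s", type_raw, nct),
          "trialpubs_parse_error")
  )
  ref_df <- function(xp, type) {
    pmids <- txts(paste0(xp, "/PMID"))
    data.frame(pmid = pmids, type = rep(type, length(pmids)),
               stringsAsFactors = FALSE)
  }
  refs <- rbind(ref_df("results_reference", "result_reference"),
                ref_df("reference", "background"),
                ref_df("derived_reference", "derived"))
  vc <- txt("version_count")
  study_record(
    nct_id = nct,
    brief_title = txt("brief_title"),
    official_title = txt("official_title"),
    study_type = study_type,
    overall_status = .map_enum(txt("overall_status"), .status_from_legacy,
                               "overall_status", default = "unknown"),
    phase = .map_enum(txt("phase"), .phase_from_legacy, "phase", default = "na"),
    start_date = txt("start_date"),
    primary_completion_date = txt("primary_completion_date"),
    completion_date = txt("completion_date"),
    first_posted_date = txt("study_first_posted"),
    last_update_date = txt("last_update_posted"),
    version_count = if (is.na(vc)) 1L else as.integer(vc),
    interventions = data.frame(
      name = txts("intervention/intervention_name"),
      type = tolower(txts("intervention/intervention_type")),
      stringsAsFactors = FALSE),
    conditions = txts("condition"),
    lead_sponsor = txt("sponsors/lead_sponsor/agency"),
    collaborator_sponsors = txts("sponsors/collaborator/agency"),
    site_countries = unique(txts("location/facility/address/country")),
    references = refs,
    has_deposited_results = !is.na(txt("results_first_submitted")),
    why_stopped = txt("why_stopped")
  )
}

#' Read a file of registry study records
#'
#' Reads a paged bundle (`{"studies": [...]}`), a single study object, or a
#' JSON array for the API v2 dialect; a `<clinical_studies>` bundle or a
#' single `<clinical_study>` document for the legacy dialect. A record
#' without an NCT accession is rejected with its index in the file.
#'
#' @param path file path.
#' @inheritParams parse_study_record
#' @param era_floor passed to [study_table()] validation.
#' @return a validated `study_table`.
#' @export
read_study_records <- function(path, dialect = c("api_v2_json", "legacy_xml"),
                               era_floor = as.Date("1999-01-01")) {
  dialect <- match.arg(dialect)
  if (dialect == "api_v2_json") {
    doc <- jsonlite::fromJSON(path, simplifyVector = FALSE)
    raws <- if (!is.null(doc$studies)) doc$studies
            else if (!is.null(doc$protocolSection)) list(doc)
            else doc
  } else {
    doc <- xml2::read_xml(path)
    raws <- if (xml2::xml_name(doc) == "clinical_study") list(doc)
            else as.list(xml2::xml_find_all(doc, "//clinical_study"))
  }
  recs <- vector("list", length(raws))
  for (i in seq_along(raws)) {
    recs[[i]] <- tryCatch(parse_study_record(raws[[i]], dialect),
      trialpubs_parse_error = function(e) {
        abort(sprintf("record %d in %s: %s", i, path, conditionMessage(e)),
              "trialpubs_parse_error")
      })
  }
  study_table(recs, era_floor = era_floor)
}
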