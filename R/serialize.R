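# Serializers: the inverse of the two registry parsers and the article
# parser. Used by the synthetic-corpus generator to emit files, and tested
# corpus-wide via the parse(serialize(x)) == x round-trip property.

.status_to_api <- stats::setNames(names(.status_from_api), .status_from_api)
.status_to_legacy <- stats::setNames(names(.status_from_legacy), .status_from_legacy)
.phase_to_legacy <- stats::setNames(names(.phase_from_legacy), .phase_from_legacy)
.reftype_to_api <- stats::setNames(names(.reftype_from_api), .reftype_from_api)

.phase_to_api_list <- function(phase) {
  switch(phase,
    na = list("NA"), early_phase_1 = list("EARLY_PHASE1"),
    phase_1 = list("PHASE1"), phase_1_2 = list("PHASE1", "PHASE2"),
    phase_2 = list("PHASE2"), phase_2_3 = list("PHASE2", "PHASE3"),
    phase_3 = list("PHASE3"), phase_4 = list("PHASE4"))
}

# legacy registry exports print dates as "March 5, 2020" / "March 2020"
.legacy_date <- function(date, precision) {
  if (is.na(date) || precision == "missing") return(NA_character_)
  lt <- as.POSIXlt(date)
  switch(precision,
    day = sprintf("%s %d, %d", month.name[lt$mon + 1L], lt$mday, lt$year + 1900L),
    month = sprintf("%s %d", month.name[lt$mon + 1L], lt$year + 1900L),
    year = sprintf("%d", lt$year + 1900L))
}

#' Write registry study records
#'
#' Serializes a study table to a paged API v2 JSON bundle
#' (`{"studies": [...]}`) or a legacy `<clinical_studies>` XML bundle.
#' `write_study_records` and [read_study_records()] are inverse maps: every
#' field round-trips, including date precision.
#'
#' @param studies a `study_table`.
#' @param path output file path.
#' @param dialect `"api_v2_json"` or `"legacy_xml"`.
#' @return `path`, invisibly.
#' @export
write_study_records <- function(studies, path, dialect = c("api_v2_json", "legacy_xml")) {
  dialect <- match.arg(dialect)
  if (dialect == "api_v2_json") write_studies_api_json(studies, path)
  else write_studies_legacy_xml(studies, path)
  invisible(path)
}

write_studies_api_json <- function(studies, path) {
  one <- function(i) {
    s <- studies[i, ]
    dstruct <- function(d, p) {
      f <- format_partial_date(s[[d]], s[[p]])
      if (is.na(f)) NULL else list(date = f)
    }
    iv <- s$interventions[[1]]
    refs <- s$references[[1]]
    spon <- s$collaborator_sponsors[[1]]
    countries <- s$site_countries[[1]]
    status <- list(
      overallStatus = unname(.status_to_api[s$overall_status]),
      startDateStruct = dstruct("start_date", "start_date_precision"),
      primaryCompletionDateStruct = dstruct("primary_completion_date",
                                            "primary_completion_date_precision"),
      completionDateStruct = dstruct("completion_date", "completion_date_precision"),
      studyFirstPostDateStruct = dstruct("first_posted_date", "first_posted_date_precision"),
      lastUpdatePostDateStruct = dstruct("last_update_date", "last_update_date_precision")
    )
    if (!is.na(s$why_stopped)) status$whyStopped <- s$why_stopped
    idm <- list(nctId = s$nct_id, briefTitle = s$brief_title)
    if (!is.na(s$official_title)) idm$officialTitle <- s$official_title
    dm <- list(
      studyType = switch(s$study_type, interventional = "INTERVENTIONAL",
                         "OBSERVATIONAL"),
      phases = .phase_to_api_list(s$phase))
    if (s$study_type == "patient_registry") dm$patientRegistry <- TRUE
    sponsors <- list()
    if (!is.na(s$lead_sponsor)) sponsors$leadSponsor <- list(name = s$lead_sponsor)
    if (length(spon)) sponsors$collaborators <- lapply(spon, function(x) list(name = x))
    list(
      protocolSection = list(
        identificationModule = idm,
        statusModule = Filter(Negate(is.null), status),
        designModule = dm,
        conditionsModule = list(conditions = as.list(s$conditions[[1]])),
        armsInterventionsModule = list(
          interventions = lapply(seq_len(nrow(iv)), function(j)
            list(type = toupper(iv$type[j]), name = iv$name[j]))),
        sponsorCollaboratorsModule = sponsors,
        contactsLocationsModule = list(
          locations = lapply(countries, function(ct) list(country = ct))),
        referencesModule = list(
          references = lapply(seq_len(nrow(refs)), function(j)
            list(pmid = refs$pmid[j], type = unname(.reftype_to_api[refs$type[j]]))))
      ),
      hasResults = s$has_deposited_results,
      versionCount = s$version_count
    )
  }
  bundle <- list(studies = lapply(seq_len(nrow(studies)), one))
  jsonlite::write_json(bundle, path, auto_unbox = TRUE, null = "null")
}

write_studies_legacy_xml <- function(studies, path) {
  root <- xml2::xml_new_root("clinical_studies")
  for (i in seq_len(nrow(studies))) {
    s <- studies[i, ]
    cs <- xml2::xml_add_child(root, "clinical_study")
    add <- function(parent, name, value) {
      if (length(value) == 1L && !is.na(value) && nzchar(value))
        xml2::xml_add_child(parent, name, value)
    }
    idi <- xml2::xml_add_child(cs, "id_info")
    add(idi, "nct_id", s$nct_id)
    add(cs, "brief_title", s$brief_title)
    add(cs, "official_title", s$official_title)
    sp <- xml2::xml_add_child(cs, "sponsors")
    ls_ <- xml2::xml_add_child(sp, "lead_sponsor")
    add(ls_, "agency", s$lead_sponsor)
    for (co in s$collaborator_sponsors[[1]]) {
      cn <- xml2::xml_add_child(sp, "collaborator")
      add(cn, "agency", co)
    }
    add(cs, "overall_status", .status_to_legacy[s$overall_status])
    add(cs, "why_stopped", s$why_stopped)
    add(cs, "phase", .phase_to_legacy[s$phase])
    add(cs, "study_type", switch(s$study_type,
      interventional = "Interventional", observational = "Observational",
      patient_registry = "Observational [Patient Registry]"))
    add(cs, "start_date", .legacy_date(s$start_date, s$start_date_precision))
    add(cs, "primary_completion_date",
        .legacy_date(s$primary_completion_date, s$primary_completion_date_precision))
    add(cs, "completion_date",
        .legacy_date(s$completion_date, s$completion_date_precision))
    for (cond in s$conditions[[1]]) add(cs, "condition", cond)
    iv <- s$interventions[[1]]
    for (j in seq_len(nrow(iv))) {
      ivn <- xml2::xml_add_child(cs, "intervention")
      add(ivn, "intervention_type", paste0(toupper(substr(iv$type[j], 1, 1)),
                                           substr(iv$type[j], 2, nchar(iv$type[j]))))
      add(ivn, "intervention_name", iv$name[j])
    }
    for (ct in s$site_countries[[1]]) {
      loc <- xml2::xml_add_child(cs, "location")
      fac <- xml2::xml_add_child(loc, "facility")
      adr <- xml2::xml_add_child(fac, "address")
      add(adr, "country", ct)
    }
    refs <- s$references[[1]]
    for (j in seq_len(nrow(refs))) {
      el <- switch(refs$type[j], result_reference = "results_reference",
                   background = "reference", derived = "derived_reference")
      rn <- xml2::xml_add_child(cs, el)
      add(rn, "PMID", refs$pmid[j])
    }
    if (s$has_deposited_results) {
      rfs <- .legacy_date(s$last_update_date, s$last_update_date_precision)
      add(cs, "results_first_submitted",
          if (is.na(rfs)) "January 1, 2021" else rfs)
    }
    add(cs, "study_first_posted",
        .legacy_date(s$first_posted_date, s$first_posted_date_precision))
    add(cs, "last_update_posted",
        .legacy_date(s$last_update_date, s$last_update_date_precision))
    add(cs, "version_count", as.character(s$version_count))
  }
  xml2::write_xml(root, path)
}

#' Write a PubMed EFetch-style article set
#'
#' Inverse of [read_article_records()]; fields and date precision
#' round-trip.
#'
#' @param articles an `article_table`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_article_records <- function(articles, path) {
  root <- xml2::xml_new_root("PubmedArticleSet")
  for (i in seq_len(nrow(articles))) {
    a <- articles[i, ]
    pa <- xml2::xml_add_child(root, "PubmedArticle")
    mc <- xml2::xml_add_child(pa, "MedlineCitation")
    xml2::xml_add_child(mc, "PMID", a$pmid)
    art <- xml2::xml_add_child(mc, "Article")
    jr <- xml2::xml_add_child(art, "Journal")
    if (!is.na(a$journal)) xml2::xml_add_child(jr, "Title", a$journal)
    ji <- xml2::xml_add_child(jr, "JournalIssue")
    pd <- xml2::xml_add_child(ji, "PubDate")
    if (!is.na(a$publication_date) && a$publication_date_precision != "missing") {
      lt <- as.POSIXlt(a$publication_date)
      xml2::xml_add_child(pd, "Year", sprintf("%d", lt$year + 1900L))
      if (a$publication_date_precision %in% c("day", "month"))
        xml2::xml_add_child(pd, "Month", month.name[lt$mon + 1L])
      if (a$publication_date_precision == "day")
        xml2::xml_add_child(pd, "Day", sprintf("%d", lt$mday))
    }
    if (!is.na(a$title)) xml2::xml_add_child(art, "ArticleTitle", a$title)
    pt <- a$publication_types[[1]]
    if (length(pt)) {
      ptl <- xml2::xml_add_child(art, "PublicationTypeList")
      for (p in pt) xml2::xml_add_child(ptl, "PublicationType", p)
    }
    sid <- a$secondary_ids[[1]]
    if (nrow(sid)) {
      dbl <- xml2::xml_add_child(art, "DataBankList")
      for (bank in unique(sid$databank)) {
        db <- xml2::xml_add_child(dbl, "DataBank")
        xml2::xml_add_child(db, "DataBankName", bank)
        al <- xml2::xml_add_child(db, "AccessionNumberList")
        for (acc in sid$accession[sid$databank == bank])
          xml2::xml_add_child(al, "AccessionNumber", acc)
      }
    }
    mh <- a$mesh_terms[[1]]
    if (length(mh)) {
      mhl <- xml2::xml_add_child(mc, "MeshHeadingList")
      for (m in mh) {
        h <- xml2::xml_add_child(mhl, "MeshHeading")
        xml2::xml_add_child(h, "DescriptorName", m)
      }
    }
  }
  xml2::write_xml(root, path)
  invisible(path)
}
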