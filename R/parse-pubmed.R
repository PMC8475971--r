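# Bibliographic article parsing: PubMed EFetch XML. The DataBank list (the
# "secondary identifier" metadata field) is what carries cited trial
# accessions and drives the abstract-linking route.

#' Parse one PubMed article record
#'
#' Maps a `<PubmedArticle>` element onto the article-table schema.
#' Publication types and secondary identifiers are preserved verbatim.
#' Structured `<PubDate>` dates and free-text `<MedlineDate>` values are
#' resolved by [resolve_partial_date()]; an unparseable date keeps the
#' record, marks the date missing, and emits a warning.
#'
#' @param raw_record an XML string or an `xml2` node for one
#'   `<PubmedArticle>` element.
#' @return one-row `article_table`.
#' @export
parse_article_record <- function(raw_record) {
  node <- if (inherits(raw_record, "xml_node")) raw_record else
    xml2::xml_find_first(xml2::read_xml(raw_record), "//PubmedArticle")
  if (inherits(node, "xml_missing"))
    abort("malformed article record: no <PubmedArticle> element", "trialpubs_parse_error")
  txt <- function(xp) {
    n <- xml2::xml_find_first(node, xp)
    if (inherits(n, "xml_missing")) NA_character_ else trimws(xml2::xml_text(n))
  }
  txts <- function(xp) trimws(xml2::xml_text(xml2::xml_find_all(node, xp)))
  pmid <- txt("MedlineCitation/PMID")
  if (is.na(pmid) || !nzchar(pmid))
    abort("article record rejected: missing <PMID>", "trialpubs_parse_error")

  pub_date <- pubmed_date_string(node)
  pd <- tryCatch(resolve_partial_date(pub_date), trialpubs_parse_error = function(e) {
    warning(sprintf("PMID %s: %s; keeping record with missing date",
                    pmid, conditionMessage(e)), call. = FALSE)
    resolve_partial_date(NA_character_)
  })

  banks <- xml2::xml_find_all(node, "MedlineCitation/Article/DataBankList/DataBank")
  sid <- do.call(rbind, lapply(banks, function(b) {
    nm <- xml2::xml_text(xml2::xml_find_first(b, "DataBankName"))
    acc <- xml2::xml_text(xml2::xml_find_all(b, "AccessionNumberList/AccessionNumber"))
    if (length(acc) == 0L) return(NULL)
    data.frame(databank = rep(trimws(nm), length(acc)), accession = trimws(acc),
               stringsAsFactors = FALSE)
  }))

  out <- article_record(
    pmid = pmid,
    title = txt("MedlineCitation/Article/ArticleTitle"),
    journal = txt("MedlineCitation/Article/Journal/Title"),
    publication_types = txts("MedlineCitation/Article/PublicationTypeList/PublicationType"),
    secondary_ids = sid,
    mesh_terms = txts("MedlineCitation/MeshHeadingList/MeshHeading/DescriptorName")
  )
  out$publication_date <- pd$date
  out$publication_date_precision <- pd$precision
  out
}

# Assemble a partial-date string from <PubDate> (Year/Month/Day) or the
# free-text <MedlineDate> ("2021 Jul-Aug", "2020 Nov 9"); ranges resolve to
# their first month.
pubmed_date_string <- function(node) {
  pd <- xml2::xml_find_first(node, "MedlineCitation/Article/Journal/JournalIssue/PubDate")
  if (inherits(pd, "xml_missing")) return(NA_character_)
  el <- function(nm) {
    n <- xml2::xml_find_first(pd, nm)
    if (inherits(n, "xml_missing")) NA_character_ else trimws(xml2::xml_text(n))
  }
  y <- el("Year"); m <- el("Month"); d <- el("Day")
  if (!is.na(y)) {
    if (grepl("^\\d+$", m %||% "")) m <- month.name[as.integer(m)]
    if (is.na(m)) return(y)
    if (is.na(d)) return(paste(m, y))
    return(sprintf("%s %s, %s", m, d, y))
  }
  ml <- el("MedlineDate")
  if (is.na(ml) || !nzchar(ml)) return(NA_character_)
  tok <- strsplit(trimws(ml), "\\s+")[[1]]
  if (!grepl("^\\d{4}", tok[1])) return(ml)  # let the resolver report it
  y <- substr(tok[1], 1, 4)
  m <- if (length(tok) >= 2) sub("-.*$", "", tok[2]) else NA_character_
  d <- if (length(tok) >= 3) sub("-.*$", "", tok[3]) else NA_character_
  if (is.na(m)) y
  else if (is.na(d) || !grepl("^\\d+$", d)) paste(m, y)
  else sprintf("%s %s, %s", m, d, y)
}

#' Read a PubMed EFetch XML article set
#'
#' @param path file path to a `<PubmedArticleSet>` document.
#' @return a validated `article_table`.
#' @export
read_article_records <- function(path) {
  doc <- xml2::read_xml(path)
  nodes <- xml2::xml_find_all(doc, "//PubmedArticle")
  recs <- vector("list", length(nodes))
  for (i in seq_along(nodes)) {
    recs[[i]] <- tryCatch(parse_article_record(nodes[[i]]),
      trialpubs_parse_error = function(e) {
        abort(sprintf("record %d in %s: %s", i, path, conditionMessage(e)),
              "trialpubs_parse_error")
      })
  }
  article_table(recs)
}
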