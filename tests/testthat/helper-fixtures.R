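# Shared fixtures, built in code at test time.

# sorted (trial, article) pair keys, for set comparisons
pair_key <- function(d) sort(paste(d$nct_id, d$pmid))

# memoized mid-size synthetic corpus shared across test files
.fixture_env <- new.env(parent = emptyenv())
shared_corpus <- function() {
  if (is.null(.fixture_env$corpus)) {
    spec <- corpus_spec(n_interventional = 150L, n_observational = 40L,
                        n_registry = 10L, seed = 42L)
    .fixture_env$corpus <- generate_corpus(spec)
  }
  .fixture_env$corpus
}

tiny_study <- function(nct = "NCT01234567", status = "completed",
                       phase = "phase_3", title = "Trial of Drug X in COVID-19",
                       conditions = "COVID-19", ...) {
  study_record(nct_id = nct, brief_title = title, study_type = "interventional",
               overall_status = status, phase = phase, conditions = conditions,
               ...)
}

minimal_api_json <- function(nct = "NCT00000001") {
  sprintf('{
    "protocolSection": {
      "identificationModule": {"nctId": "%s", "briefTitle": "Minimal"},
      "statusModule": {"overallStatus": "RECRUITING"},
      "designModule": {"studyType": "INTERVENTIONAL"}
    }
  }', nct)
}

legacy_xml_record <- function(nct = "NCT00000002", phase = "Phase 2/Phase 3",
                              extra = "") {
  sprintf('<clinical_study>
    <id_info><nct_id>%s</nct_id></id_info>
    <brief_title>A Trial</brief_title>
    <overall_status>Completed</overall_status>
    <phase>%s</phase>
    <study_type>Interventional</study_type>
    %s
  </clinical_study>', nct, phase, extra)
}

pubmed_xml <- function(pmid = "32459919", inner = "", pubdate = "<Year>2020</Year><Month>December</Month><Day>1</Day>",
                       types = "<PublicationType>Journal Article</PublicationType>") {
  sprintf('<PubmedArticleSet><PubmedArticle><MedlineCitation>
    <PMID>%s</PMID>
    <Article>
      <Journal><Title>N Engl J Med</Title><JournalIssue><PubDate>%s</PubDate></JournalIssue></Journal>
      <ArticleTitle>An article title.</ArticleTitle>
      <PublicationTypeList>%s</PublicationTypeList>
      %s
    </Article>
  </MedlineCitation></PubmedArticle></PubmedArticleSet>', pmid, pubdate, types, inner)
}

databank_xml <- function(accessions) {
  sprintf('<DataBankList><DataBank><DataBankName>ClinicalTrials.gov</DataBankName>
    <AccessionNumberList>%s</AccessionNumberList></DataBank></DataBankList>',
    paste(sprintf("<AccessionNumber>%s</AccessionNumber>", accessions), collapse = ""))
}
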