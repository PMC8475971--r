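# Seeded synthetic-corpus generator with ground-truth annotations, so every
# pipeline stage is testable offline. The generator emulates the statistical
# structure the analysis assumes — two link routes with overlap, backdated
# (misclassified) registry references, protocol vs. result vs. editorial
# articles, update-count variation, positive publication lags — not the
# covariance structure of real sponsor behaviour.

#' Synthetic corpus specification
#'
#' Defaults describe a surveillance scenario matching the observed mixture
#' in large condition cohorts: most studies on-condition, ~13% of cohort
#' trials registry-linked and ~16% abstract-linked with a small both-routes
#' overlap, publication lags averaging 149 days (sd 40, truncated at 1 day),
#' 17% never-updated records, a quarter of studies with a US site, and ~11%
#' vaccine-titled trials.
#'
#' @param n_interventional,n_observational,n_registry study counts per type.
#' @param keyword_hit_rate probability a study is on-condition.
#' @param status_distribution named probabilities over [study_statuses()].
#' @param phase_distribution named probabilities over [study_phases()]
#'   (interventional studies only).
#' @param intervention_pool character vector of intervention name variants
#'   (free-text style, may carry dose tokens and synonyms).
#' @param p_registry_link,p_abstract_link,p_both per-cohort-trial link-route
#'   probabilities; `p_both` is the probability the same article is found by
#'   both routes and cannot exceed either route probability.
#' @param p_misclassified_backdate probability a cohort trial carries a
#'   backdated (misclassified) registry result reference.
#' @param p_protocol_article,p_other_article article-class mix for planted
#'   links (remainder are result articles).
#' @param vaccine_title_rate probability an interventional trial title
#'   mentions a vaccine.
#' @param us_site_rate probability of at least one United States site.
#' @param update_count_distribution named probabilities over record version
#'   counts.
#' @param lag_mean_days,lag_sd_days publication-lag distribution (normal,
#'   truncated below at 1 day).
#' @param seed master seed; each record category draws from its own stream
#'   derived from it, so adding studies of one type does not perturb
#'   another type's draws.
#' @return object of class `corpus_spec`.
#' @export
corpus_spec <- function(n_interventional = 300L, n_observational = 80L,
                        n_registry = 20L, keyword_hit_rate = 0.8,
                        status_distribution = c(
                          recruiting = 0.35, active_not_recruiting = 0.12,
                          enrolling_by_invitation = 0.03, completed = 0.30,
                          terminated = 0.05, suspended = 0.02,
                          withdrawn = 0.03, not_yet_recruiting = 0.08,
                          unknown = 0.02),
                        phase_distribution = c(
                          na = 0.25, early_phase_1 = 0.03, phase_1 = 0.10,
                          phase_1_2 = 0.08, phase_2 = 0.25, phase_2_3 = 0.07,
                          phase_3 = 0.15, phase_4 = 0.07),
                        intervention_pool = c(
                          "Hydroxychloroquine", "Hydroxychloroquine 200mg",
                          "Remdesivir", "Tocilizumab", "Ivermectin",
                          "Azithromycin", "Dexamethasone", "Convalescent Plasma",
                          "anti-SARS-CoV-2 convalescent plasma", "Colchicine",
                          "Vitamin D", "Lopinavir/Ritonavir", "Favipiravir",
                          "Baricitinib", "Interferon Beta-1a"),
                        p_registry_link = 0.13, p_abstract_link = 0.16,
                        p_both = 0.02, p_misclassified_backdate = 0.10,
                        p_protocol_article = 0.12, p_other_article = 0.08,
                        vaccine_title_rate = 0.11, us_site_rate = 0.25,
                        update_count_distribution = c(
                          "1" = 0.17, "2" = 0.13, "3" = 0.22, "4" = 0.16,
                          "5" = 0.12, "6" = 0.08, "8" = 0.07, "11" = 0.05),
                        lag_mean_days = 149, lag_sd_days = 40, seed = 1L) {
  spec <- list(n_interventional = assert_scalar_count(n_interventional, "n_interventional"),
               n_observational = assert_scalar_count(n_observational, "n_observational"),
               n_registry = assert_scalar_count(n_registry, "n_registry"),
               keyword_hit_rate = keyword_hit_rate,
               status_distribution = status_distribution,
               phase_distribution = phase_distribution,
               intervention_pool = intervention_pool,
               p_registry_link = p_registry_link,
               p_abstract_link = p_abstract_link, p_both = p_both,
               p_misclassified_backdate = p_misclassified_backdate,
               p_protocol_article = p_protocol_article,
               p_other_article = p_other_article,
               vaccine_title_rate = vaccine_title_rate,
               us_site_rate = us_site_rate,
               update_count_distribution = update_count_distribution,
               lag_mean_days = lag_mean_days, lag_sd_days = lag_sd_days,
               seed = as.integer(seed))
  probs <- c(keyword_hit_rate, p_registry_link, p_abstract_link, p_both,
             p_misclassified_backdate, p_protocol_article, p_other_article,
             vaccine_title_rate, us_site_rate)
  if (any(probs < 0 | probs > 1))
    abort("all corpus probabilities must lie in [0, 1]", "trialpubs_config_error")
  if (p_both > min(p_registry_link, p_abstract_link))
    abort("infeasible corpus spec: p_both exceeds a route probability",
          "trialpubs_config_error")
  for (d in c("status_distribution", "phase_distribution",
              "update_count_distribution"))
    if (abs(sum(spec[[d]]) - 1) > 1e-8)
      abort(sprintf("%s must sum to 1", d), "trialpubs_config_error")
  if (!all(names(status_distribution) %in% study_statuses()) ||
      !all(names(phase_distribution) %in% study_phases()))
    abort("distribution names must be valid enum values", "trialpubs_config_error")
  structure(spec, class = "corpus_spec")
}

# run code under a category-specific RNG stream derived from the master
# seed, restoring the caller's RNG state afterwards
with_stream <- function(seed, offset, code) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (is.null(old)) suppressWarnings(rm(".Random.seed", envir = globalenv()))
          else assign(".Random.seed", old, envir = globalenv()))
  set.seed(seed %% 2000000000L + offset)
  force(code)
}

.decoy_conditions <- c("Influenza", "Type 2 Diabetes Mellitus",
                       "Breast Cancer", "Hypertension", "Asthma")
.countries <- c("United States", "France", "Brazil", "China", "Spain",
                "United Kingdom", "India", "Iran")
.sponsors <- c("University of Oxford", "Assistance Publique - Hopitaux de Paris",
               "National Institute of Allergy and Infectious Diseases",
               "Gilead Sciences", "ModernaTX, Inc.", "Mayo Clinic",
               "Cairo University", "University of Minnesota",
               "Hospital Universitario Austral", "Capital Medical University")
.why_stopped_pool <- list(
  recruitment = c("Unable to recruit participants",
                  "Slow enrollment due to declining case counts",
                  "Study stopped for poor accrual"),
  safety = c("Stopped due to safety concerns",
             "Increased adverse events in treatment arm"),
  futility = c("Stopped for futility at interim analysis",
               "Lack of efficacy observed"),
  external_results = c("Results from other trials made continuation unnecessary",
                       "Terminated because standard of care changed"),
  other = c("Funding withdrawn", "Sponsor decision")
)

.generate_studies <- function(spec, type, n, offset, nct_start) {
  if (n == 0L) return(list(records = NULL, truth = NULL))
  with_stream(spec$seed, offset, {
    recs <- vector("list", n)
    truth <- vector("list", n)
    for (i in seq_len(n)) {
      nct <- sprintf("NCT%08d", nct_start + i)
      hit <- stats::runif(1) < spec$keyword_hit_rate
      status <- sample(names(spec$status_distribution), 1,
                       prob = spec$status_distribution)
      phase <- if (type == "interventional")
        sample(names(spec$phase_distribution), 1, prob = spec$phase_distribution)
      else "na"
      start <- as.Date("2020-01-01") + sample.int(450L, 1) - 1L
      timing_draw <- stats::runif(1)
      ended <- status %in% c("completed", "terminated")
      completion <- if (ended) start + sample(60:400, 1) else
        if (stats::runif(1) < 0.5) start + sample(300:900, 1) else as.Date(NA)
      pcd <- if (!is.na(completion) && stats::runif(1) < 0.8)
        completion - sample(0:60, 1) else as.Date(NA)
      first_posted <- if (timing_draw < 0.45) start - sample.int(60L, 1)
        else if (timing_draw < 0.88 || is.na(completion))
          start + sample.int(90L, 1)
        else completion + sample.int(60L, 1)
      vc <- as.integer(sample(names(spec$update_count_distribution), 1,
                              prob = spec$update_count_distribution))
      last_update <- first_posted + sample.int(300L, 1)
      vaccine <- type == "interventional" && stats::runif(1) < spec$vaccine_title_rate
      iv_names <- if (type == "interventional")
        sample(spec$intervention_pool, sample(1:2, 1)) else character()
      condition <- if (hit) sample(c("COVID-19", "SARS-CoV-2 Infection"), 1)
        else sample(.decoy_conditions, 1)
      title_subject <- if (vaccine) "a Vaccine Candidate"
        else if (hit && length(iv_names)) iv_names[1]  # off-condition titles
        else "an Investigational Strategy"             # must not leak keywords
      title <- sprintf("%s of %s in %s (%s)",
                       if (type == "interventional") "Trial" else "Study",
                       title_subject, condition, nct)
      countries <- unique(c(if (stats::runif(1) < spec$us_site_rate) "United States",
                            sample(.countries[-1], sample(1:2, 1))))
      term_cat <- NA_character_
      why <- NA_character_
      if (status == "terminated") {
        if (stats::runif(1) < 0.87) {
          term_cat <- sample(names(.why_stopped_pool), 1)
          why <- sample(.why_stopped_pool[[term_cat]], 1)
        } else term_cat <- "unspecified"
      }
      recs[[i]] <- study_record(
        nct_id = nct, brief_title = title,
        official_title = paste("Official:", title),
        study_type = type, overall_status = status, phase = phase,
        start_date = format(start, "%Y-%m-%d"),
        primary_completion_date = if (is.na(pcd)) NULL else format(pcd, "%Y-%m-%d"),
        completion_date = if (is.na(completion)) NULL else format(completion, "%Y-%m-%d"),
        first_posted_date = format(first_posted, "%Y-%m-%d"),
        last_update_date = format(last_update, "%Y-%m-%d"),
        version_count = vc,
        interventions = if (length(iv_names))
          data.frame(name = iv_names, type = "drug", stringsAsFactors = FALSE)
        else NULL,
        conditions = condition,
        lead_sponsor = sample(.sponsors, 1),
        collaborator_sponsors = if (stats::runif(1) < 0.3) sample(.sponsors, 1) else character(),
        site_countries = countries,
        has_deposited_results = stats::runif(1) < 0.03,
        why_stopped = if (is.na(why)) NULL else why)
      truth[[i]] <- data.frame(
        nct_id = nct, study_type = type, keyword_hit = hit,
        status_eligible = NA, is_vaccine_trial = vaccine,
        termination_category = term_cat, stringsAsFactors = FALSE)
    }
    list(records = recs, truth = do.call(rbind, truth))
  })
}

#' Generate a seeded synthetic corpus with ground truth
#'
#' Emits registry study records (both dialects), PubMed-style article
#' records, and a ground-truth annotation set: planted links with their
#' routes, planted backdated (misclassified) registry references, true
#' article classes, cohort membership, vaccine flags, termination
#' categories, and publication lags. Deterministic given `spec$seed`.
#' Backdated references always get a publication date strictly before the
#' trial start; genuine links get lags from the spec's truncated-normal lag
#' distribution.
#'
#' @param spec a [corpus_spec()].
#' @param dir optional directory: when given, writes
#'   `studies_api.json`, `studies_legacy.xml`, `articles.xml`, and
#'   ground-truth CSV sidecars there.
#' @param eligible_statuses statuses treated as cohort-eligible when
#'   planting links (links are planted only for cohort members, whose
#'   recovery the pipeline is tested against).
#' @return list: `studies` (`study_table`), `articles` (`article_table`),
#'   `truth` (list of ground-truth data.frames), `files` (paths written,
#'   or `NULL`).
#' @export
generate_corpus <- function(spec, dir = NULL,
                            eligible_statuses = c("recruiting",
                                                  "active_not_recruiting",
                                                  "enrolling_by_invitation",
                                                  "completed", "terminated")) {
  stopifnot(inherits(spec, "corpus_spec"))
  gi <- .generate_studies(spec, "interventional", spec$n_interventional, 1L, 40000000L)
  go <- .generate_studies(spec, "observational", spec$n_observational, 2L, 41000000L)
  gr <- .generate_studies(spec, "patient_registry", spec$n_registry, 3L, 42000000L)
  studies <- study_table(c(gi$records, go$records, gr$records))
  cohort_truth <- rbind(gi$truth, go$truth, gr$truth)
  cohort_truth$status_eligible <-
    studies$overall_status %in% eligible_statuses
  cohort_truth$in_cohort <- cohort_truth$keyword_hit & cohort_truth$status_eligible

  with_stream(spec$seed, 4L, {
    members <- which(cohort_truth$in_cohort)
    arts <- list(); links <- list(); backdated <- list(); lags <- list()
    planted_classes <- list()
    pmid_next <- 33000001L
    new_pmid <- function() {
      p <- as.character(pmid_next); pmid_next <<- pmid_next + 1L; p
    }
    make_article <- function(study_i, cls, pub_date, cite_nct) {
      nct <- studies$nct_id[study_i]
      iv <- studies$interventions[[study_i]]
      subj <- if (nrow(iv)) iv$name[1] else "observation"
      pmid <- new_pmid()
      title <- switch(cls,
        protocol = sprintf("Study Protocol: %s for COVID-19 (%s)", subj, pmid),
        other = sprintf("Comment on %s trials (%s)", subj, pmid),
        sprintf("Efficacy of %s in COVID-19: a randomized trial (%s)", subj, pmid))
      types <- switch(cls,
        protocol = c("Clinical Trial Protocol", "Journal Article"),
        other = c(sample(c("Editorial", "Comment", "Letter"), 1), "Journal Article"),
        c("Journal Article", "Randomized Controlled Trial"))
      article_record(
        pmid = pmid, title = title,
        journal = sample(c("Lancet", "N Engl J Med", "Trials", "PLoS One",
                           "JAMA Netw Open"), 1),
        publication_date = format(pub_date, "%Y-%m-%d"),
        publication_types = types,
        secondary_ids = if (is.null(cite_nct)) NULL else
          data.frame(databank = "ClinicalTrials.gov", accession = cite_nct,
                     stringsAsFactors = FALSE),
        mesh_terms = c("COVID-19", "SARS-CoV-2"))
    }
    for (i in members) {
      nct <- studies$nct_id[i]
      start <- studies$start_date[i]
      u <- stats::runif(1)
      route <- if (u < spec$p_both) "both"
        else if (u < spec$p_abstract_link) "abstract"
        else if (u < spec$p_abstract_link + spec$p_registry_link - spec$p_both)
          "registry"
        else "none"
      if (route != "none") {
        lag <- max(1, round(stats::rnorm(1, spec$lag_mean_days, spec$lag_sd_days)))
        cls_u <- stats::runif(1)
        cls <- if (cls_u < spec$p_protocol_article) "protocol"
          else if (cls_u < spec$p_protocol_article + spec$p_other_article) "other"
          else "result"
        art <- make_article(i, cls, start + lag,
                            cite_nct = if (route %in% c("abstract", "both")) nct else NULL)
        arts[[length(arts) + 1L]] <- art
        planted_classes[[length(planted_classes) + 1L]] <-
          data.frame(pmid = art$pmid, class = cls, stringsAsFactors = FALSE)
        if (route %in% c("registry", "both")) {
          refs <- studies$references[[i]]
          studies$references[[i]] <- rbind(refs, data.frame(
            pmid = art$pmid, type = "result_reference", stringsAsFactors = FALSE))
        }
        src <- switch(route, both = c("registry", "abstract"), route)
        links[[length(links) + 1L]] <- data.frame(
          nct_id = nct, pmid = art$pmid, source = src, stringsAsFactors = FALSE)
        lags[[length(lags) + 1L]] <- data.frame(
          nct_id = nct, pmid = art$pmid, lag_days = lag, class = cls,
          stringsAsFactors = FALSE)
      }
      if (!is.na(start) && stats::runif(1) < spec$p_misclassified_backdate) {
        pub <- start - sample(30:400, 1)
        art <- make_article(i, "result", pub, cite_nct = NULL)
        arts[[length(arts) + 1L]] <- art
        planted_classes[[length(planted_classes) + 1L]] <-
          data.frame(pmid = art$pmid, class = "result", stringsAsFactors = FALSE)
        refs <- studies$references[[i]]
        studies$references[[i]] <- rbind(refs, data.frame(
          pmid = art$pmid, type = "result_reference", stringsAsFactors = FALSE))
        backdated[[length(backdated) + 1L]] <- data.frame(
          nct_id = nct, pmid = art$pmid, stringsAsFactors = FALSE)
      }
      # occasional background reference: must never become a link
      if (stats::runif(1) < 0.10) {
        art <- make_article(i, "other", start + sample(1:200, 1), cite_nct = NULL)
        arts[[length(arts) + 1L]] <- art
        planted_classes[[length(planted_classes) + 1L]] <-
          data.frame(pmid = art$pmid, class = "other", stringsAsFactors = FALSE)
        refs <- studies$references[[i]]
        studies$references[[i]] <- rbind(refs, data.frame(
          pmid = art$pmid, type = "background", stringsAsFactors = FALSE))
      }
    }
    articles <- if (length(arts)) article_table(arts) else article_table(list())
    truth <- list(
      true_links = if (length(links)) do.call(rbind, links) else
        data.frame(nct_id = character(), pmid = character(),
                   source = character(), stringsAsFactors = FALSE),
      planted_misclassified = if (length(backdated)) do.call(rbind, backdated) else
        data.frame(nct_id = character(), pmid = character(),
                   stringsAsFactors = FALSE),
      article_classes = if (length(planted_classes))
        do.call(rbind, planted_classes) else
        data.frame(pmid = character(), class = character(),
                   stringsAsFactors = FALSE),
      cohort = cohort_truth,
      lags = if (length(lags)) do.call(rbind, lags) else
        data.frame(nct_id = character(), pmid = character(),
                   lag_days = numeric(), class = character(),
                   stringsAsFactors = FALSE)
    )
    files <- NULL
    if (!is.null(dir)) {
      dir.create(dir, showWarnings = FALSE, recursive = TRUE)
      files <- c(
        json = file.path(dir, "studies_api.json"),
        xml = file.path(dir, "studies_legacy.xml"),
        articles = file.path(dir, "articles.xml"),
        links = file.path(dir, "truth_links.csv"),
        misclassified = file.path(dir, "truth_misclassified.csv"),
        cohort = file.path(dir, "truth_cohort.csv"))
      write_study_records(studies, files["json"], "api_v2_json")
      write_study_records(studies, files["xml"], "legacy_xml")
      write_article_records(articles, files["articles"])
      utils::write.csv(truth$true_links, files["links"], row.names = FALSE)
      utils::write.csv(truth$planted_misclassified, files["misclassified"],
                       row.names = FALSE)
      utils::write.csv(truth$cohort, files["cohort"], row.names = FALSE)
    }
    list(studies = studies, articles = articles, truth = truth, files = files)
  })
}

# published per-phase trial-count profiles (phase 1..4, then unphased) used
# by the fixed reference corpus
.reference_profiles <- list(
  hydroxychloroquine = c(3, 36, 54, 16, 11),
  ivermectin = c(2, 14, 16, 4, 7),
  remdesivir = c(1, 10, 26, 3, 3),
  azithromycin = c(1, 16, 17, 2, 5),
  tocilizumab = c(1, 18, 12, 3, 6),
  ritonavir = c(1, 7, 8, 8, 4),
  `vitamin d` = c(1, 6, 6, 2, 8),
  dexamethasone = c(0, 2, 13, 7, 2),
  lopinavir = c(0, 6, 8, 6, 4),
  colchicine = c(0, 9, 11, 1, 1),
  `mrna 1273` = c(3, 2, 4, 0, 0)
)

#' Fixed reference corpus with known intervention phase profiles
#'
#' A small deterministic corpus of completed COVID-19 interventional trials
#' whose per-intervention phase-count profiles equal well-known published
#' surveillance values (e.g. hydroxychloroquine 3/36/54/16/11 across phases
#' 1-4 plus unphased, tocilizumab with 12 phase-3 trials, the mRNA-1273
#' vaccine with 3/2/4 trials in phases 1-3), so intervention-score checks
#' can run end-to-end through cohort selection and profile aggregation
#' rather than only through the score formula. One phase-3 trial per
#' intervention is recorded as a combined phase 2/3 trial to exercise the
#' higher-phase promotion.
#'
#' @return list: `studies` (a `study_table`), `articles` (an empty
#'   `article_table`), `profiles_expected` (named numeric vector of the
#'   intervention significance scores implied by the planted phase counts).
#' @export
make_reference_corpus <- function() {
  phase_of <- c("phase_1", "phase_2", "phase_3", "phase_4", "na")
  recs <- list()
  k <- 0L
  for (iv in names(.reference_profiles)) {
    counts <- .reference_profiles[[iv]]
    promoted <- FALSE
    for (lvl in seq_along(counts)) {
      for (j in seq_len(counts[lvl])) {
        k <- k + 1L
        ph <- phase_of[lvl]
        if (ph == "phase_3" && !promoted) { ph <- "phase_2_3"; promoted <- TRUE }
        display <- if (iv == "mrna 1273") "mRNA-1273" else tools::toTitleCase(iv)
        recs[[k]] <- study_record(
          nct_id = sprintf("NCT%08d", 43000000L + k),
          brief_title = sprintf("Trial of %s in COVID-19 (#%d)", display, k),
          study_type = "interventional", overall_status = "completed",
          phase = ph,
          start_date = format(as.Date("2020-03-01") + (k %% 300), "%Y-%m-%d"),
          first_posted_date = format(as.Date("2020-02-15") + (k %% 300), "%Y-%m-%d"),
          completion_date = format(as.Date("2020-12-01") + (k %% 300), "%Y-%m-%d"),
          version_count = 1L + (k %% 5L),
          interventions = data.frame(name = display, type = "drug",
                                     stringsAsFactors = FALSE),
          conditions = "COVID-19",
          lead_sponsor = sprintf("Sponsor %d", 1L + (k %% 37L)),
          site_countries = if (k %% 4L == 0L) c("United States", "France") else "France")
      }
    }
  }
  expected <- vapply(.reference_profiles, function(counts)
    intervention_significance_score(stats::setNames(
      c(counts[5], counts[1:4]), as.character(0:4))), numeric(1))
  list(studies = study_table(recs), articles = article_table(list()),
       profiles_expected = expected)
}
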