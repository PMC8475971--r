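# Intervention significance scoring and the publication attention score.

#' Normalize a free-text intervention name
#'
#' Registry interventions are free text; the same drug appears under dose
#' qualifiers, punctuation variants, and synonyms. Normalization:
#' lowercase; punctuation to space; whitespace collapsed; leading/trailing
#' dose tokens (numbers with mg/ml/iu-style units) stripped; a configurable
#' synonym map applied last.
#'
#' @param name character vector of intervention names.
#' @param synonyms named character vector mapping normalized raw strings to
#'   canonical strings.
#' @return character vector of canonical names.
#' @export
#' @examples
#' normalize_intervention("Hydroxychloroquine 200mg")  # "hydroxychloroquine"
normalize_intervention <- function(name, synonyms = character()) {
  combined_re <- "^[0-9]+([.][0-9]+)?(mg|ml|iu|mcg|ug|g)$"  # "200mg"
  number_re <- "^[0-9]+([.][0-9]+)?$"
  unit_re <- "^(mg|ml|iu|mcg|ug|g)$"
  strip_edge <- function(toks, pick, drop2) {
    # pick: index of edge token; drop from the edge while a dose is found
    repeat {
      n <- length(toks)
      if (n <= 1L) return(toks)
      e1 <- toks[pick(n)]
      if (grepl(combined_re, e1)) { toks <- toks[-pick(n)]; next }
      if (n > 2L) {
        # "200 mg" as two tokens, in reading order at either end
        e2 <- toks[drop2(n)]
        if ((grepl(unit_re, e1) && grepl(number_re, e2)) ||
            (grepl(number_re, e1) && grepl(unit_re, e2))) {
          toks <- toks[-c(pick(n), drop2(n))]; next
        }
      }
      return(toks)
    }
  }
  vapply(name, function(x) {
    if (is.na(x)) abort("intervention name is NA", "trialpubs_validation_error")
    s <- tolower(x)
    s <- gsub("[^a-z0-9.]+", " ", s)  # keep dots so "0.2 mg" stays one number
    toks <- strsplit(trimws(s), " +")[[1]]
    toks <- gsub("^[.]+|[.]+$", "", toks)
    toks <- toks[nzchar(toks)]
    toks <- strip_edge(toks, pick = function(n) n, drop2 = function(n) n - 1L)
    toks <- strip_edge(toks, pick = function(n) 1L, drop2 = function(n) 2L)
    out <- paste(toks, collapse = " ")
    if (!nzchar(out) || grepl(combined_re, out) || grepl(number_re, out) ||
        grepl(unit_re, out))
      abort(sprintf("intervention name empty after normalization: '%s'", x),
            "trialpubs_validation_error")
    if (out %in% names(synonyms)) out <- unname(synonyms[[out]])
    out
  }, character(1), USE.NAMES = FALSE)
}

#' Intervention significance score
#'
#' For each phase level with at least one trial, add the phase value plus
#' 0.01 per trial in that phase; sum over levels. Phase values are the
#' phase number for phases 1-4; unphased (level 0) trials contribute at
#' value 1 — a weight derived by reconstruction from published per-phase
#' count/score tables rather than stated anywhere, and configurable via
#' `na_value`. Combined phases must already be promoted with
#' [effective_phase()].
#'
#' @param phase_counts named numeric vector or list: names are phase levels
#'   `"0"`..`"4"`, values trial counts. Levels with zero trials contribute
#'   nothing.
#' @param na_value phase value of unphased (level 0) trials.
#' @return score (full precision; print with 2 decimals).
#' @export
#' @examples
#' intervention_significance_score(c("3" = 12))            # 3.12
#' intervention_significance_score(c("1" = 3, "2" = 2, "3" = 4))  # 6.09
intervention_significance_score <- function(phase_counts, na_value = 1) {
  counts <- unlist(phase_counts)
  if (length(counts) == 0L) return(0)
  if (is.null(names(counts)) || !all(names(counts) %in% as.character(0:4)))
    abort("phase_counts must be named with levels 0..4", "trialpubs_validation_error")
  if (any(counts < 0)) abort("negative trial count", "trialpubs_validation_error")
  lev <- as.integer(names(counts))
  value <- ifelse(lev == 0L, na_value, lev)
  sum((value + 0.01 * counts)[counts > 0])
}

#' Aggregate per-intervention profiles across a cohort
#'
#' Normalizes intervention names, counts trials per effective phase level,
#' counts distinct lead sponsors and linked publications, and computes the
#' significance score for every intervention in the cohort.
#'
#' @param studies the cohort `study_table` (interventional trials).
#' @param links optional master link data.frame; publication counts are
#'   links attached to the intervention's trials.
#' @param synonyms synonym map for [normalize_intervention()].
#' @param na_value passed to [intervention_significance_score()].
#' @return data.frame, one row per canonical intervention: `intervention`,
#'   `trial_count`, `phase_0`..`phase_4`, `significance_score`,
#'   `sponsor_count`, `publication_count`.
#' @export
intervention_profiles <- function(studies, links = NULL,
                                  synonyms = character(), na_value = 1) {
  rows <- lapply(seq_len(nrow(studies)), function(i) {
    iv <- studies$interventions[[i]]
    if (nrow(iv) == 0L) return(NULL)
    data.frame(intervention = normalize_intervention(iv$name, synonyms),
               nct_id = studies$nct_id[i],
               phase_level = effective_phase(studies$phase[i]),
               lead_sponsor = studies$lead_sponsor[i],
               stringsAsFactors = FALSE)
  })
  rows <- unique(do.call(rbind, rows))
  if (is.null(rows) || nrow(rows) == 0L)
    return(data.frame(intervention = character(), trial_count = integer(),
                      phase_0 = integer(), phase_1 = integer(),
                      phase_2 = integer(), phase_3 = integer(),
                      phase_4 = integer(), significance_score = numeric(),
                      sponsor_count = integer(), publication_count = integer(),
                      stringsAsFactors = FALSE))
  pubs_per_trial <- if (is.null(links)) integer(0) else table(links$nct_id)
  out <- do.call(rbind, lapply(split(rows, rows$intervention), function(g) {
    counts <- table(factor(g$phase_level, levels = 0:4))
    pc <- stats::setNames(as.numeric(counts), as.character(0:4))
    data.frame(
      intervention = g$intervention[1],
      trial_count = nrow(g),
      phase_0 = as.integer(pc["0"]), phase_1 = as.integer(pc["1"]),
      phase_2 = as.integer(pc["2"]), phase_3 = as.integer(pc["3"]),
      phase_4 = as.integer(pc["4"]),
      significance_score = intervention_significance_score(pc, na_value),
      sponsor_count = length(unique(g$lead_sponsor[!is.na(g$lead_sponsor)])),
      publication_count = sum(as.integer(pubs_per_trial[g$nct_id]), na.rm = TRUE),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}

#' Publication attention score
#'
#' Composite ranking score for one trial-article link:
#' \deqn{w_{type}(class) \times (phase + b_{US} 1[US] +
#'   \min(u (v - 1), cap) + w_{rec} e^{-age/\tau} + w_{int} I)}
#' where `phase` is the trial's effective phase (0 for observational
#' studies and registries), `v` the record version count, `age` the article
#' age in days at `as_of`, and `I` the intervention significance score
#' normalized to the corpus maximum. A missing publication date zeroes the
#' recency term and is flagged.
#'
#' @param article_class `result`, `protocol`, or `other`.
#' @param phase_level effective phase, 0..4.
#' @param has_us_site logical.
#' @param version_count registry record versions including the initial one.
#' @param publication_date [Date] (NA allowed).
#' @param intervention_norm intervention significance normalized to [0, 1]
#'   (0 when the study has no interventions).
#' @param weights an [attention_weights()].
#' @param as_of scoring date.
#' @return data.frame with the total `attention_score`, each component
#'   (`phase_term`, `us_term`, `update_term`, `recency_term`,
#'   `intervention_term`, `type_multiplier`), and `recency_missing`.
#' @export
attention_score <- function(article_class, phase_level, has_us_site,
                            version_count, publication_date,
                            intervention_norm, weights = attention_weights(),
                            as_of = Sys.Date()) {
  n <- max(length(article_class), length(phase_level), length(has_us_site),
           length(version_count), length(publication_date),
           length(intervention_norm))
  article_class <- rep_len(article_class, n)
  phase_level <- rep_len(phase_level, n)
  has_us_site <- rep_len(has_us_site, n)
  version_count <- rep_len(version_count, n)
  publication_date <- rep_len(publication_date, n)
  intervention_norm <- rep_len(intervention_norm, n)
  if (any(is.na(article_class)) ||
      !all(article_class %in% names(weights$type_weight)))
    abort("article_class must be one of result/protocol/other",
          "trialpubs_validation_error")
  if (any(intervention_norm < 0 | intervention_norm > 1))
    abort("intervention_norm must lie in [0, 1]", "trialpubs_validation_error")
  age <- as.numeric(as_of - publication_date)
  recency_missing <- is.na(age)
  recency <- ifelse(recency_missing, 0,
                    weights$recency_weight * exp(-age / weights$recency_scale))
  update <- pmin(weights$update_unit * (version_count - 1L), weights$update_cap)
  us <- weights$us_bonus * as.numeric(has_us_site)
  interv <- weights$intervention_weight * intervention_norm
  mult <- unname(weights$type_weight[article_class])
  data.frame(
    attention_score = mult * (phase_level + us + update + recency + interv),
    type_multiplier = mult, phase_term = phase_level, us_term = us,
    update_term = update, recency_term = recency,
    intervention_term = interv, recency_missing = recency_missing
  )
}

#' Score every link in a master link set
#'
#' Joins study attributes and intervention significance onto the link set
#' and evaluates [attention_score()] per link. A study's intervention
#' significance is the maximum across its interventions; normalization is
#' by the corpus-wide maximum (observational studies and registries get 0).
#'
#' @param links master link data.frame (with `article_class`).
#' @param studies the cohort `study_table`.
#' @param profiles output of [intervention_profiles()], or `NULL` to
#'   compute it.
#' @param synonyms,weights,as_of see [intervention_profiles()] and
#'   [attention_score()].
#' @param focus_country country defining the site bonus.
#' @return links with score components appended, unranked.
#' @export
score_publications <- function(links, studies, profiles = NULL,
                               synonyms = character(),
                               weights = attention_weights(),
                               as_of = Sys.Date(),
                               focus_country = "United States") {
  if (is.null(profiles)) profiles <- intervention_profiles(studies, links, synonyms)
  score_max <- if (nrow(profiles)) max(profiles$significance_score) else 0
  study_sig <- vapply(seq_len(nrow(studies)), function(i) {
    iv <- studies$interventions[[i]]
    if (nrow(iv) == 0L || score_max == 0) return(0)
    canon <- normalize_intervention(iv$name, synonyms)
    s <- profiles$significance_score[match(canon, profiles$intervention)]
    max(c(s, 0), na.rm = TRUE) / score_max
  }, numeric(1))
  idx <- match(links$nct_id, studies$nct_id)
  has_us <- vapply(idx, function(i)
    focus_country %in% studies$site_countries[[i]], logical(1))
  cls <- links$article_class
  cls[is.na(cls)] <- "result"  # unresolvable article metadata: neutral class
  comp <- attention_score(
    article_class = cls,
    phase_level = ifelse(studies$study_type[idx] == "interventional",
                         effective_phase(studies$phase[idx]), 0L),
    has_us_site = has_us,
    version_count = studies$version_count[idx],
    publication_date = links$publication_date,
    intervention_norm = study_sig[idx],
    weights = weights, as_of = as_of)
  cbind(links, has_us_site = has_us, version_count = studies$version_count[idx],
        effective_phase = effective_phase(studies$phase[idx]), comp)
}

#' Rank scored publications
#'
#' Sorts by attention score descending; ties broken by publication date
#' descending (later first), then PMID ascending. Ranks are assigned 1..N.
#'
#' @param scored output of [score_publications()].
#' @return the same data.frame, sorted, with a `rank` column.
#' @export
rank_publications <- function(scored) {
  dt <- as.numeric(scored$publication_date)
  dt[is.na(dt)] <- -Inf
  pm <- suppressWarnings(as.numeric(scored$pmid))
  ord <- order(-scored$attention_score, -dt,
               if (anyNA(pm)) scored$pmid else pm)
  out <- scored[ord, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' Prioritized shortlist
#'
#' Retains ranked links that are result articles from phase-3 trials with
#' at least one focus-country site and multiple registry record updates
#' (at least `min_updates` beyond the initial registration). Order is
#' preserved; the operation is idempotent.
#'
#' @param ranked output of [rank_publications()].
#' @param min_updates minimum updates beyond initial registration
#'   (default 2, i.e. version_count >= 3).
#' @return the qualifying sublist, in rank order.
#' @export
shortlist <- function(ranked, min_updates = 2L) {
  keep <- ranked$article_class %in% "result" &
    ranked$effective_phase == 3L &
    ranked$has_us_site &
    (ranked$version_count - 1L) >= min_updates
  out <- ranked[keep & !is.na(keep), , drop = FALSE]
  rownames(out) <- NULL
  out
}
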