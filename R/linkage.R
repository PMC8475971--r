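# Trial-article linkage: the registry route (result references inside the
# study record), the abstract route (trial accessions in PubMed secondary
# identifiers), misclassified-reference filtering, and the merged master
# link set with its accounting identities.

.empty_links <- function() {
  data.frame(nct_id = character(), pmid = character(), source = character(),
             stringsAsFactors = FALSE)
}

#' Extract registry-route links from study records
#'
#' One link per `result_reference` entry in each study record; background
#' and derived references are ignored. References without a PMID are
#' skipped with a warning.
#'
#' @param studies a `study_table`.
#' @return data.frame: `nct_id`, `pmid`, `source` (= `"registry"`),
#'   deduplicated on (nct_id, pmid).
#' @export
extract_registry_links <- function(studies) {
  out <- lapply(seq_len(nrow(studies)), function(i) {
    refs <- studies$references[[i]]
    refs <- refs[refs$type == "result_reference", , drop = FALSE]
    nopmid <- is.na(refs$pmid) | !nzchar(refs$pmid)
    if (any(nopmid))
      warning(sprintf("%s: %d result reference(s) without a PMID skipped",
                      studies$nct_id[i], sum(nopmid)), call. = FALSE)
    refs <- refs[!nopmid, , drop = FALSE]
    if (nrow(refs) == 0L) return(NULL)
    data.frame(nct_id = studies$nct_id[i], pmid = refs$pmid,
               source = "registry", stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_links())
  unique(out)
}

#' Remove misclassified registry result references
#'
#' A registry-route link is misclassified when its article was published
#' strictly before the trial started — it cannot report results of that
#' trial. Same-day publication is kept (the boundary is strict). Links whose
#' publication or start date is unresolvable are conservatively kept and
#' flagged `undatable`; the abstract route is never subject to this filter.
#'
#' @param links registry-route links (from [extract_registry_links()]).
#' @param articles an `article_table` indexable by the links' PMIDs.
#' @param studies a `study_table` indexable by the links' accessions.
#' @return list with `kept` and `removed` link data.frames; both carry an
#'   `undatable` flag column, and `removed` retains the offending dates for
#'   audit.
#' @export
filter_misclassified <- function(links, articles, studies) {
  if (nrow(links) == 0L)
    return(list(kept = cbind(links, undatable = logical(0)),
                removed = cbind(links, undatable = logical(0))))
  pub <- articles$publication_date[match(links$pmid, articles$pmid)]
  start <- studies$start_date[match(links$nct_id, studies$nct_id)]
  undatable <- is.na(pub) | is.na(start)
  removed <- !undatable & pub < start
  out <- links
  out$undatable <- undatable
  out$publication_date <- pub
  out$trial_start_date <- start
  list(kept = out[!removed, , drop = FALSE],
       removed = out[removed, , drop = FALSE])
}

#' Find abstract-route links via secondary identifiers
#'
#' One link per (article, cited cohort accession) pair: an article whose
#' ClinicalTrials.gov secondary identifiers cite k cohort trials yields k
#' links. Accessions outside the cohort are ignored.
#'
#' @param articles an `article_table`.
#' @param cohort_ncts character vector of cohort accessions.
#' @return data.frame: `nct_id`, `pmid`, `source` (= `"abstract"`).
#' @export
find_abstract_links <- function(articles, cohort_ncts) {
  out <- lapply(seq_len(nrow(articles)), function(i) {
    sid <- articles$secondary_ids[[i]]
    acc <- unique(sid$accession[sid$databank == "ClinicalTrials.gov"])
    acc <- acc[acc %in% cohort_ncts]
    if (length(acc) == 0L) return(NULL)
    data.frame(nct_id = acc, pmid = articles$pmid[i], source = "abstract",
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out)) return(.empty_links())
  unique(out)
}

#' Classify an article as result, protocol, or other
#'
#' Protocol-typed articles, or articles whose title contains "study
#' protocol", are `protocol`; editorials, comments, letters, and reviews
#' are `other`; everything else — including unknown publication-type
#' strings — is `result`. Precedence when types conflict: protocol > other
#' > result, so a protocol tag always wins.
#'
#' @param articles an `article_table`.
#' @return character vector, one class per article.
#' @export
classify_article <- function(articles) {
  other_types <- c("editorial", "comment", "letter", "review",
                   "published erratum", "retraction of publication")
  vapply(seq_len(nrow(articles)), function(i) {
    types <- tolower(articles$publication_types[[i]])
    title <- tolower(articles$title[i] %||% "")
    if (any(grepl("protocol", types, fixed = TRUE)) ||
        (!is.na(title) && grepl("study protocol", title, fixed = TRUE)))
      return("protocol")
    if (any(types %in% other_types)) return("other")
    "result"
  }, character(1))
}

#' Merge the two link routes into the master link set
#'
#' Deduplicates on (nct_id, pmid): a pair found by both routes appears once
#' with both sources, counts once among distinct pairs, and contributes to
#' the both-routes overlap count. The same article across different trials
#' is deliberately kept as separate links (surveillance counts trial-article
#' combinations); articles are deduplicated only in `n_distinct_articles`.
#'
#' @param registry_kept registry-route links surviving
#'   [filter_misclassified()].
#' @param abstract_links abstract-route links.
#' @param articles optional `article_table`; when given, links carry the
#'   article class and publication date.
#' @param n_removed count of misclassified links removed upstream, echoed
#'   into the accounting.
#' @return list with `links` (master data.frame: `nct_id`, `pmid`,
#'   `source_registry`, `source_abstract`, and when resolvable
#'   `article_class`, `publication_date`) and `accounting` (see
#'   [link_accounting()]).
#' @export
merge_links <- function(registry_kept, abstract_links, articles = NULL,
                        n_removed = 0L) {
  reg <- unique(registry_kept[, c("nct_id", "pmid")])
  abs_ <- unique(abstract_links[, c("nct_id", "pmid")])
  key <- function(d) paste(d$nct_id, d$pmid)
  all_pairs <- unique(rbind(reg, abs_))
  links <- data.frame(
    nct_id = all_pairs$nct_id, pmid = all_pairs$pmid,
    source_registry = key(all_pairs) %in% key(reg),
    source_abstract = key(all_pairs) %in% key(abs_),
    stringsAsFactors = FALSE
  )
  pm <- suppressWarnings(as.numeric(links$pmid))
  links <- links[order(links$nct_id, if (anyNA(pm)) links$pmid else pm), ,
                 drop = FALSE]
  rownames(links) <- NULL
  if (!is.null(articles)) {
    idx <- match(links$pmid, articles$pmid)
    cls <- rep(NA_character_, nrow(articles))
    if (nrow(articles)) cls <- classify_article(articles)
    links$article_class <- cls[idx]
    links$publication_date <- articles$publication_date[idx]
  }
  list(links = links,
       accounting = link_accounting(links, n_removed = n_removed))
}

#' Link-set accounting
#'
#' Counts (link, route) combinations, per-route totals, both-route overlap,
#' distinct (trial, article) pairs, and distinct articles. The identities
#' `n_abstract + n_registry == n_combinations` and
#' `n_distinct_pairs == n_abstract + n_registry - n_both` hold by
#' construction and are verified on every call.
#'
#' @param links a master link data.frame from [merge_links()].
#' @param n_removed count of misclassified registry links removed upstream.
#' @return list of counts (class `link_accounting`).
#' @export
link_accounting <- function(links, n_removed = 0L) {
  n_registry <- sum(links$source_registry)
  n_abstract <- sum(links$source_abstract)
  n_both <- sum(links$source_registry & links$source_abstract)
  acc <- list(
    n_combinations = n_abstract + n_registry,
    n_abstract = n_abstract,
    n_registry = n_registry,
    n_both = n_both,
    n_distinct_pairs = nrow(links),
    n_distinct_articles = length(unique(links$pmid)),
    n_removed_misclassified = as.integer(n_removed)
  )
  stopifnot(acc$n_abstract + acc$n_registry == acc$n_combinations,
            acc$n_distinct_pairs == acc$n_abstract + acc$n_registry - acc$n_both,
            acc$n_distinct_articles <= acc$n_distinct_pairs)
  structure(acc, class = "link_accounting")
}

#' @export
print.link_accounting <- function(x, ...) {
  cat(sprintf(paste0(
    "trial-article link accounting\n",
    "  (link, route) combinations: %d\n",
    "  abstract-route: %d   registry-route: %d   both routes: %d\n",
    "  distinct (trial, article) pairs: %d\n",
    "  distinct articles: %d\n",
    "  registry references removed as misclassified: %d\n"),
    x$n_combinations, x$n_abstract, x$n_registry, x$n_both,
    x$n_distinct_pairs, x$n_distinct_articles, x$n_removed_misclassified))
  invisible(x)
}

#' Build the full master link set for a cohort
#'
#' Runs both routes, the misclassification filter, and the merge in one
#' call.
#'
#' @param studies the cohort `study_table`.
#' @param articles an `article_table`.
#' @return list: `links`, `accounting`, `removed` (audit list of
#'   misclassified registry links).
#' @export
build_links <- function(studies, articles) {
  reg <- extract_registry_links(studies)
  flt <- filter_misclassified(reg, articles, studies)
  abs_ <- find_abstract_links(articles, studies$nct_id)
  merged <- merge_links(flt$kept, abs_, articles = articles,
                        n_removed = nrow(flt$removed))
  c(merged, list(removed = flt$removed))
}
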