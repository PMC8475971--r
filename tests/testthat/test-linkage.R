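test_that("registry links come only from result references", {
  refs <- data.frame(pmid = c("111", "222", "333"),
                     type = c("result_reference", "background", "background"),
                     stringsAsFactors = FALSE)
  s <- study_table(list(tiny_study(references = refs)))
  links <- extract_registry_links(s)
  expect_equal(nrow(links), 1L)
  expect_equal(links$pmid, "111")
  expect_equal(links$source, "registry")

  expect_equal(nrow(extract_registry_links(study_table(list(tiny_study())))), 0L)
})

test_that("result references without a PMID are skipped with a warning", {
  refs <- data.frame(pmid = c("111", ""), type = rep("result_reference", 2),
                     stringsAsFactors = FALSE)
  s <- study_table(list(tiny_study(references = refs)))
  expect_warning(links <- extract_registry_links(s), "without a PMID")
  expect_equal(links$pmid, "111")
})

test_that("misclassification filter removes strictly pre-start publications only", {
  s <- study_table(list(tiny_study("NCT00000001", start_date = "2020-03-01")))
  arts <- article_table(list(
    article_record("1", publication_date = "2019-05-01"),
    article_record("2", publication_date = "2020-03-01"),  # boundary: kept
    article_record("3", publication_date = "2020-09-01"),
    article_record("4")                                    # undatable: kept
  ))
  links <- data.frame(nct_id = "NCT00000001", pmid = as.character(1:4),
                      source = "registry", stringsAsFactors = FALSE)
  flt <- filter_misclassified(links, arts, s)
  expect_equal(flt$removed$pmid, "1")
  expect_setequal(flt$kept$pmid, c("2", "3", "4"))
  expect_equal(flt$kept$undatable[flt$kept$pmid == "4"], TRUE)
  # idempotent, output subset of input
  again <- filter_misclassified(flt$kept[, c("nct_id", "pmid", "source")], arts, s)
  expect_equal(nrow(again$removed), 0L)
  expect_setequal(again$kept$pmid, flt$kept$pmid)
})

test_that("abstract links multiply per cited cohort accession", {
  cohort <- c("NCT00000001", "NCT00000002", "NCT00000003")
  arts <- article_table(list(
    article_record("10", secondary_ids = data.frame(
      databank = "ClinicalTrials.gov", accession = "NCT00000001")),
    article_record("11", secondary_ids = data.frame(
      databank = "ClinicalTrials.gov", accession = "NCT99999999")),
    article_record("12", secondary_ids = data.frame(
      databank = rep("ClinicalTrials.gov", 3), accession = cohort)),
    article_record("13", secondary_ids = data.frame(
      databank = "GenBank", accession = "AB123456"))
  ))
  links <- find_abstract_links(arts, cohort)
  expect_equal(sum(links$pmid == "10"), 1L)
  expect_equal(sum(links$pmid == "11"), 0L)
  expect_equal(sum(links$pmid == "12"), 3L)
  expect_equal(sum(links$pmid == "13"), 0L)
})

test_that("article classification follows protocol > other > result precedence", {
  arts <- article_table(list(
    article_record("1", publication_types = c("Randomized Controlled Trial",
                                              "Journal Article")),
    article_record("2", publication_types = "Editorial"),
    article_record("3", title = "Thing: a Study Protocol",
                   publication_types = "Journal Article"),
    article_record("4", publication_types = c("Clinical Trial Protocol",
                                              "Editorial")),
    article_record("5", publication_types = "Some Unknown Type")
  ))
  expect_equal(classify_article(arts),
               c("result", "other", "protocol", "protocol", "result"))
})

test_that("merging deduplicates pairs and satisfies the accounting identities", {
  reg <- data.frame(nct_id = "NCT00000001", pmid = c("B", "C"),
                    stringsAsFactors = FALSE)
  abs_ <- data.frame(nct_id = "NCT00000001", pmid = c("A", "B"),
                     stringsAsFactors = FALSE)
  m <- merge_links(reg, abs_)
  expect_setequal(m$links$pmid, c("A", "B", "C"))
  expect_equal(m$accounting$n_both, 1L)
  expect_equal(m$accounting$n_distinct_pairs, 3L)
  both <- m$links[m$links$pmid == "B", ]
  expect_true(both$source_registry && both$source_abstract)
})

test_that("published route counts satisfy the distinct-pair identity", {
  # 418 abstract + 342 registry with 11 overlapping pairs -> 749 distinct
  abs_ <- data.frame(nct_id = sprintf("NCT%08d", seq_len(418)),
                     pmid = as.character(seq_len(418)), stringsAsFactors = FALSE)
  reg <- data.frame(nct_id = sprintf("NCT%08d", 408 + seq_len(342)),
                    pmid = as.character(408 + seq_len(342)),
                    stringsAsFactors = FALSE)  # pairs 409..418 + pmid overlap
  m <- merge_links(reg, abs_)
  expect_equal(m$accounting$n_abstract, 418L)
  expect_equal(m$accounting$n_registry, 342L)
  expect_equal(m$accounting$n_both, 10L)
  expect_equal(m$accounting$n_distinct_pairs, 418L + 342L - 10L)
  expect_equal(m$accounting$n_combinations, 760L)
})

test_that("merge output equals a brute-force nested-loop construction", {
  g <- shared_corpus()
  cohort <- select_cohort(g$studies, cohort_config())
  link_set <- build_links(cohort, g$articles)
  # oracle: enumerate every (trial, article, route) triple directly
  oracle <- list()
  for (i in seq_len(nrow(cohort))) {
    for (j in seq_len(nrow(g$articles))) {
      nct <- cohort$nct_id[i]; pmid <- g$articles$pmid[j]
      refs <- cohort$references[[i]]
      if (pmid %in% refs$pmid[refs$type == "result_reference"]) {
        pub <- g$articles$publication_date[j]
        if (is.na(pub) || is.na(cohort$start_date[i]) ||
            pub >= cohort$start_date[i])
          oracle[[length(oracle) + 1L]] <- c(nct, pmid, "registry")
      }
      sid <- g$articles$secondary_ids[[j]]
      if (nct %in% sid$accession[sid$databank == "ClinicalTrials.gov"])
        oracle[[length(oracle) + 1L]] <- c(nct, pmid, "abstract")
    }
  }
  oracle <- as.data.frame(do.call(rbind, oracle), stringsAsFactors = FALSE)
  names(oracle) <- c("nct_id", "pmid", "source")
  got <- rbind(
    data.frame(nct_id = link_set$links$nct_id[link_set$links$source_registry],
               pmid = link_set$links$pmid[link_set$links$source_registry],
               source = "registry", stringsAsFactors = FALSE),
    data.frame(nct_id = link_set$links$nct_id[link_set$links$source_abstract],
               pmid = link_set$links$pmid[link_set$links$source_abstract],
               source = "abstract", stringsAsFactors = FALSE))
  expect_setequal(paste(got$nct_id, got$pmid, got$source),
                  paste(oracle$nct_id, oracle$pmid, oracle$source))
})

test_that("the pipeline recovers planted links and removes exactly the planted backdated set", {
  g <- shared_corpus()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"))
  expect_equal(pair_key(res$links),
               pair_key(unique(g$truth$true_links[, c("nct_id", "pmid")])))
  expect_equal(pair_key(res$removed), pair_key(g$truth$planted_misclassified))
  # route sources agree with planted truth
  tl <- g$truth$true_links
  reg_true <- pair_key(tl[tl$source == "registry", c("nct_id", "pmid")])
  expect_equal(pair_key(res$links[res$links$source_registry,
                                  c("nct_id", "pmid")]), reg_true)
  # conservation identity
  acc <- res$accounting
  expect_equal(acc$n_abstract + acc$n_registry - acc$n_both, nrow(res$links))
})
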