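test_that("intervention names normalize through case, punctuation, dose, synonyms", {
  expect_equal(normalize_intervention("Hydroxychloroquine 200mg"),
               "hydroxychloroquine")
  expect_equal(normalize_intervention("Remdesivir"), "remdesivir")
  expect_equal(normalize_intervention("Ivermectin 0.2 mg"), "ivermectin")
  expect_equal(normalize_intervention("mRNA-1273"), "mrna 1273")  # bare numbers kept
  expect_equal(normalize_intervention("Lopinavir/Ritonavir"), "lopinavir ritonavir")
  syn <- c("anti sars cov 2 convalescent plasma" = "convalescent plasma",
           "hcq" = "hydroxychloroquine")
  expect_equal(normalize_intervention("Anti-SARS-CoV-2 Convalescent Plasma", syn),
               "convalescent plasma")
  expect_equal(normalize_intervention("HCQ", syn), "hydroxychloroquine")
  expect_error(normalize_intervention("200mg"), "empty after normalization")
})

test_that("the significance score is phase value plus 0.01 per trial, summed over occupied phases", {
  expect_equal(intervention_significance_score(c("3" = 12)), 3.12)
  expect_equal(intervention_significance_score(c("1" = 3, "2" = 2, "3" = 4)), 6.09)
  expect_equal(
    intervention_significance_score(c("1" = 3, "2" = 36, "3" = 54, "4" = 16, "0" = 11)),
    12.20)
  expect_equal(intervention_significance_score(numeric()), 0)
  expect_equal(intervention_significance_score(c("2" = 0, "3" = 1)), 3.01)
  expect_error(intervention_significance_score(c("3" = -1)), "negative")
  expect_error(intervention_significance_score(c("7" = 1)), "levels 0..4")
})

test_that("score monotonicity: +0.01 within a phase, value + 0.01 for a new phase", {
  set.seed(9)
  for (rep in 1:25) {
    counts <- stats::setNames(sample(0:20, 5, replace = TRUE), as.character(0:4))
    base <- intervention_significance_score(counts)
    lvl <- sample(0:4, 1)
    bumped <- counts
    bumped[as.character(lvl)] <- bumped[as.character(lvl)] + 1
    delta <- intervention_significance_score(bumped) - base
    if (counts[as.character(lvl)] > 0) expect_equal(delta, 0.01)
    else expect_equal(delta, max(lvl, 1) + 0.01)
  }
})

test_that("profiles aggregate phase counts, sponsors and publications per canonical intervention", {
  studies <- study_table(list(
    tiny_study("NCT00000001", phase = "phase_2_3",
               interventions = data.frame(name = "Drug X 10mg", type = "drug"),
               lead_sponsor = "A"),
    tiny_study("NCT00000002", phase = "phase_3",
               interventions = data.frame(name = "drug x", type = "drug"),
               lead_sponsor = "B"),
    tiny_study("NCT00000003", phase = "phase_1",
               interventions = data.frame(name = "Drug X", type = "drug"),
               lead_sponsor = "A")
  ))
  links <- data.frame(nct_id = c("NCT00000001", "NCT00000001", "NCT00000003"),
                      pmid = c("1", "2", "3"), stringsAsFactors = FALSE)
  p <- intervention_profiles(studies, links)
  expect_equal(nrow(p), 1L)
  expect_equal(p$intervention, "drug x")
  expect_equal(p$trial_count, 3L)
  expect_equal(p$phase_3, 2L)  # phase_2_3 promoted
  expect_equal(p$phase_1, 1L)
  expect_equal(p$significance_score, 1.01 + 3.02)
  expect_equal(p$sponsor_count, 2L)
  expect_equal(p$publication_count, 3L)
})

test_that("attention score matches its closed form and component breakdown", {
  w <- attention_weights()
  r <- attention_score("result", 3L, TRUE, 11L, Sys.Date(), 1.0, w, Sys.Date())
  expect_equal(r$attention_score, 3.95)
  expect_equal(r$update_term, 0.10)
  expect_equal(r$recency_term, 0.25)
  p <- attention_score("protocol", 3L, TRUE, 11L, Sys.Date(), 1.0, w, Sys.Date())
  expect_equal(p$attention_score, 1.975)
  z <- attention_score("result", 0L, FALSE, 1L, Sys.Date() - 100000L, 0, w, Sys.Date())
  expect_equal(z$attention_score, 0, tolerance = 1e-12)
  m <- attention_score("result", 2L, FALSE, 1L, as.Date(NA), 0, w, Sys.Date())
  expect_true(m$recency_missing)
  expect_equal(m$recency_term, 0)
})

test_that("attention score is monotone in each driver and decreasing in age", {
  w <- attention_weights()
  as_of <- as.Date("2021-08-15")
  base <- function(...) attention_score(..., weights = w, as_of = as_of)$attention_score
  ref <- base("result", 2L, FALSE, 3L, as_of - 100, 0.5)
  expect_gt(base("result", 3L, FALSE, 3L, as_of - 100, 0.5), ref)
  expect_gt(base("result", 2L, TRUE, 3L, as_of - 100, 0.5), ref)
  expect_gt(base("result", 2L, FALSE, 10L, as_of - 100, 0.5), ref)
  expect_gt(base("result", 2L, FALSE, 3L, as_of - 100, 0.9), ref)
  expect_gt(base("result", 2L, FALSE, 3L, as_of - 10, 0.5), ref)
  # update term saturates at the cap
  expect_equal(base("result", 2L, FALSE, 26L + 1L, as_of - 100, 0.5),
               base("result", 2L, FALSE, 60L, as_of - 100, 0.5))
})

test_that("with structural weights zeroed the score reduces to type weight times phase", {
  w <- attention_weights(us_bonus = 0, update_unit = 0, update_cap = 0,
                         recency_weight = 0, intervention_weight = 0)
  for (cls in c("result", "protocol", "other")) {
    s <- attention_score(cls, 3L, TRUE, 11L, Sys.Date(), 1, w, Sys.Date())
    expect_equal(s$attention_score,
                 unname(w$type_weight[cls]) * 3)
  }
})

test_that("ranking matches a brute-force stable-sort oracle on 1000 random items", {
  set.seed(101)
  n <- 1000
  scored <- data.frame(
    nct_id = sprintf("NCT%08d", sample.int(500, n, replace = TRUE)),
    pmid = as.character(sample.int(10^7, n)),
    attention_score = round(stats::runif(n, 0, 4), 2),  # force many ties
    publication_date = as.Date("2020-01-01") + sample.int(400, n, replace = TRUE),
    stringsAsFactors = FALSE)
  ranked <- rank_publications(scored)
  key <- function(d) paste(d$pmid, d$nct_id)
  # oracle: encode (-score, -date, pmid) as a lexicographically sortable
  # string and use plain string sort
  sort_key <- sprintf("%012.4f|%012.1f|%015d",
                      10^6 - scored$attention_score,
                      10^6 - as.numeric(scored$publication_date),
                      as.integer(scored$pmid))
  oracle <- scored[match(sort(sort_key, method = "radix"), sort_key), ]
  expect_equal(key(ranked), key(oracle))
  expect_equal(ranked$rank, seq_len(n))
  expect_true(all(diff(ranked$attention_score) <= 0))
  # tie rule: equal scores, later publication first
  two <- rank_publications(data.frame(
    nct_id = "NCT00000001", pmid = c("2", "1"), attention_score = 1,
    publication_date = as.Date(c("2020-01-01", "2021-01-01")),
    stringsAsFactors = FALSE))
  expect_equal(two$pmid, c("1", "2"))
})

test_that("the shortlist keeps result/phase-3/US/multiply-updated links, idempotently", {
  g <- shared_corpus()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"))
  sl <- res$shortlist
  qualifying <- res$ranked[
    res$ranked$article_class %in% "result" & res$ranked$effective_phase == 3L &
      res$ranked$has_us_site & res$ranked$version_count >= 3L, ]
  expect_equal(pair_key(sl), pair_key(qualifying))
  expect_true(all(diff(sl$rank) > 0))  # rank order preserved
  expect_equal(shortlist(sl), sl)
  # protocol articles from qualifying trials are excluded
  prot <- res$ranked[res$ranked$article_class %in% "protocol" &
                       res$ranked$effective_phase == 3L, ]
  if (nrow(prot)) expect_false(any(pair_key(prot) %in% pair_key(sl)))
})
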