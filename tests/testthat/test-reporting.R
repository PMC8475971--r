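test_that("percentages round half-up to one decimal", {
  expect_equal(percentage(419, 2669), 15.7)
  expect_equal(percentage(418, 760), 55.0)
  expect_equal(percentage(40, 290), 13.8)   # 13.793 -> 13.8 by half-up
  expect_equal(percentage(0, 10), 0.0)
  expect_equal(percentage(1, 8), 12.5)
  expect_equal(percentage(1, 800), 0.1)
  expect_error(percentage(1, 0), "positive denominator")
})

test_that("round_half_up rounds exact halves away from zero", {
  expect_equal(round_half_up(2.25, 1), 2.3)
  expect_equal(round_half_up(-2.25, 1), -2.3)
  expect_equal(round_half_up(2.24, 1), 2.2)
  expect_equal(round_half_up(0.5), 1)
})

test_that("intervention tables sort by score, then trial count, then name", {
  profiles <- data.frame(
    intervention = c("a", "b", "c", "d"),
    trial_count = c(10L, 40L, 43L, 43L),
    significance_score = c(12.2, 11.43, 11.43, 11.43),
    stringsAsFactors = FALSE)
  tab <- build_intervention_table(profiles, top_n = 3L)
  expect_equal(tab$intervention, c("a", "c", "d"))
  expect_equal(nrow(build_intervention_table(profiles[0, ])), 0L)
  expect_equal(nrow(build_intervention_table(profiles[1, ])), 1L)
})

test_that("publication lag is measured from trial start, excluding protocols", {
  s <- study_table(list(tiny_study("NCT00000001", start_date = "2020-03-02")))
  links <- data.frame(
    nct_id = "NCT00000001", pmid = c("1", "2"),
    article_class = c("result", "protocol"),
    publication_date = as.Date(c("2020-07-30", "2021-07-30")),
    stringsAsFactors = FALSE)
  st <- publication_lag_stats(links, s)
  expect_equal(st$mean_days, 150)
  expect_equal(st$n, 1L)
  expect_equal(st$n_undatable, 0L)
})

test_that("planted publication lags are recovered from the generated corpus", {
  g <- shared_corpus()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"))
  st <- publication_lag_stats(res$links, res$cohort)
  truth <- g$truth$lags
  expect_equal(st$mean_days, mean(truth$lag_days[truth$class != "protocol"]),
               tolerance = 1e-9)
})

test_that("pre-completion publications are result articles from formally incomplete trials", {
  s <- study_table(list(
    tiny_study("NCT00000001", primary_completion_date = "2022-10-27"),
    tiny_study("NCT00000002", completion_date = "2020-06-30")
  ))
  links <- data.frame(
    nct_id = c("NCT00000001", "NCT00000002"), pmid = c("1", "2"),
    article_class = "result",
    publication_date = as.Date(c("2020-12-01", "2020-12-01")),
    stringsAsFactors = FALSE)
  pc <- pre_completion_publications(links, s, as_of = as.Date("2021-08-15"))
  expect_equal(pc$links$nct_id, "NCT00000001")  # completion still in the future
  expect_equal(pc$n_links, 1L)
  expect_equal(pc$n_trials, 1L)
})

test_that("deposit crosstab partitions every corpus", {
  g <- shared_corpus()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"))
  ct <- deposit_crosstab(res$cohort, res$links)
  expect_equal(sum(ct), nrow(res$cohort))
  expect_equal(unname(ct["deposit_only"] + ct["deposit_and_article"]),
               sum(res$cohort$has_deposited_results))
  # randomized partition property
  set.seed(5)
  for (r in 1:10) {
    n <- sample(1:30, 1)
    st <- study_table(lapply(seq_len(n), function(i)
      tiny_study(sprintf("NCT%08d", i),
                 has_deposited_results = stats::runif(1) < 0.5)))
    linked <- sprintf("NCT%08d", sample.int(n, sample(0:n, 1)))
    lk <- data.frame(nct_id = linked, pmid = rep("1", length(linked)),
                     stringsAsFactors = FALSE)
    expect_equal(sum(deposit_crosstab(st, lk)), n)
  }
})

test_that("review time saved is the list-size difference at the reading rate", {
  expect_equal(review_time_saved(760, 58, 2), 23.4)
  expect_equal(review_time_saved(100, 100, 2), 0.0)
  expect_equal(review_time_saved(10, 0, 6), 1.0)
  expect_error(review_time_saved(5, 6), "larger than")
})

test_that("summary percentages are recomputable from their own counts", {
  g <- shared_corpus()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"))
  sm <- res$summary
  expect_equal(sm$pct_with_any_result_article,
               percentage(sm$n_with_any_result_article, sm$n_studies))
  expect_equal(sm$n_deposit_only + sm$n_deposit_and_article,
               sm$n_deposited_results)
  expect_equal(sm$review_hours_saved,
               review_time_saved(sm$accounting$n_combinations, sm$n_shortlist))
})

test_that("an intervention table rebuilt from the stored master CSV matches in-memory", {
  g <- shared_corpus()
  d <- withr::local_tempdir()
  res <- run_pipeline(g$studies, g$articles, as_of = as.Date("2021-08-15"),
                      out_dir = d)
  expect_true(all(file.exists(res$files)))
  stored <- utils::read.csv(
    file.path(d, "trialpubs_intervention-phase_cnts_all.csv"),
    stringsAsFactors = FALSE)
  expect_equal(build_intervention_table(stored),
               build_intervention_table(res$profiles))
  # master list round-trips the ranked links
  master <- utils::read.csv(file.path(d, "trialpubs_Master.csv"),
                            colClasses = c(pmid = "character"),
                            stringsAsFactors = FALSE)
  expect_equal(master$pmid, res$ranked$pmid)
  expect_equal(master$attention_score, res$ranked$attention_score)
})
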