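test_that("cohort selection requires a keyword hit and an eligible status", {
  cfg <- cohort_config(condition_keywords = c("covid", "sars-cov-2"))
  studies <- study_table(list(
    tiny_study("NCT00000001", status = "completed", conditions = "COVID-19",
               title = "Drug A trial"),
    tiny_study("NCT00000002", status = "completed", conditions = "Influenza",
               title = "Drug B trial"),
    tiny_study("NCT00000003", status = "withdrawn", conditions = "COVID-19",
               title = "Drug C trial"),
    tiny_study("NCT00000004", status = "recruiting", conditions = "Asthma",
               title = "SARS-CoV-2 prophylaxis")   # hit via title
  ))
  kept <- select_cohort(studies, cfg)
  expect_setequal(kept$nct_id, c("NCT00000001", "NCT00000004"))
})

test_that("cohort selection matches generator ground truth and is idempotent", {
  g <- shared_corpus()
  cfg <- cohort_config()
  kept <- select_cohort(g$studies, cfg)
  expect_setequal(kept$nct_id, g$truth$cohort$nct_id[g$truth$cohort$in_cohort])
  expect_identical(as.data.frame(select_cohort(kept, cfg)), as.data.frame(kept))
  expect_equal(nrow(select_cohort(g$studies[0, ], cfg)), 0L)
})

test_that("effective phase promotes combined phases to the higher phase", {
  expect_equal(effective_phase(c("phase_2_3", "phase_1_2", "phase_4", "na",
                                 "early_phase_1", "phase_3")),
               c(3L, 2L, 4L, 0L, 1L, 3L))
  # monotone under the phase ordering, with exactly the two promotions
  ord <- c("na", "early_phase_1", "phase_1", "phase_1_2", "phase_2",
           "phase_2_3", "phase_3", "phase_4")
  expect_false(is.unsorted(effective_phase(ord)))
  expect_error(effective_phase("phase_5"), "unknown phase")
})

test_that("vaccine trials are flagged by title keyword, matching planted truth", {
  cfg <- cohort_config()
  studies <- study_table(list(
    tiny_study("NCT00000001", title = "Study of a COVID-19 Vaccine Candidate"),
    tiny_study("NCT00000002", title = "Hydroxychloroquine Prophylaxis Trial")
  ))
  expect_equal(flag_vaccine_trials(studies, cfg), c(TRUE, FALSE))

  g <- shared_corpus()
  expect_equal(flag_vaccine_trials(g$studies, cfg),
               g$truth$cohort$is_vaccine_trial)
})

test_that("registration timing classifies prior/during/after with the stated boundaries", {
  t_of <- function(...) registration_timing(study_table(list(tiny_study(...))))
  expect_equal(t_of(first_posted_date = "2020-01-10", start_date = "2020-02-01"),
               "prior")
  expect_equal(t_of(first_posted_date = "2020-02-01", start_date = "2020-02-01"),
               "prior")  # same-day registration counts as prior
  expect_equal(t_of(first_posted_date = "2020-06-01", start_date = "2020-02-01",
                    completion_date = "2020-12-31"), "during")
  expect_equal(t_of(first_posted_date = "2021-03-01",
                    completion_date = "2020-12-31"), "after")
  expect_equal(t_of(first_posted_date = "2021-03-01"), "undetermined")
  # primary completion preferred over overall completion
  expect_equal(t_of(first_posted_date = "2021-03-01", start_date = "2020-06-01",
                    primary_completion_date = "2021-01-15",
                    completion_date = "2021-06-30"), "after")
})

test_that("timing categories partition any cohort", {
  g <- shared_corpus()
  timing <- registration_timing(g$studies)
  expect_true(all(timing %in% c("prior", "during", "after", "undetermined")))
  tab <- table(factor(timing, levels = c("prior", "during", "after", "undetermined")))
  expect_equal(sum(tab[c("prior", "during", "after")]),
               nrow(g$studies) - tab[["undetermined"]])
})

test_that("termination reasons map through the lexicon, absent text to unspecified", {
  expect_equal(categorize_termination("Unable to recruit participants"), "recruitment")
  expect_equal(categorize_termination("Stopped due to SAFETY concerns"), "safety")
  expect_equal(categorize_termination("futility at interim"), "futility")
  expect_equal(categorize_termination("results from other trials suffice"),
               "external_results")
  expect_equal(categorize_termination("budget gone"), "other")
  expect_equal(categorize_termination(NA_character_), "unspecified")
})

test_that("lexicon coverage on planted termination reasons is near-perfect", {
  g <- shared_corpus()
  truth <- g$truth$cohort
  term <- truth[!is.na(truth$termination_category), ]
  expect_gt(nrow(term), 0)
  idx <- match(term$nct_id, g$studies$nct_id)
  got <- categorize_termination(g$studies$why_stopped[idx])
  expect_gte(mean(got == term$termination_category), 0.95)
})

test_that("classify_studies assembles all per-study classifications", {
  g <- shared_corpus()
  cfg <- cohort_config()
  cohort <- select_cohort(g$studies, cfg)
  cls <- classify_studies(g$studies, cfg, cohort$nct_id)
  expect_equal(cls$in_cohort, g$truth$cohort$in_cohort)
  expect_true(all(is.na(cls$termination_category) ==
                    (g$studies$overall_status != "terminated")))
  expect_true(all(cls$effective_phase %in% 0:4))
})
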