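---
title: "Linking registered trials to result publications: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Linking registered trials to result publications: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(trialpubs)
```

## The surveillance model

A registered study can make results public three ways: a journal
article, structured summary-result deposition in the registry, or not
at all. `trialpubs` measures which of these happened for every study in
a condition cohort, using only structured metadata — no text mining of
article bodies, no manual curation. The unit of analysis is the
*(trial, article, route)* combination: the same article legitimately
links to several trials (meta-analyses, editorials), and the same pair
can be discovered by both routes.

The pipeline is: parse registry and PubMed records into two tables;
select the cohort by keyword and status; extract registry-route links
(`result_reference` entries) and abstract-route links (NCT accessions
in the PubMed DataBank "secondary identifier" field); remove
misclassified registry references; merge, score, rank, summarize.

### Assumptions

- A structured link is trustworthy evidence of a trial–article
  relationship; an *absent* link is not evidence of absence. Articles
  that never cite their NCT ID and were never registered as references
  are invisible to this method (a known negative-predictive-value
  limitation of structured links).
- A registry "result reference" published strictly before the trial
  started cannot report that trial's results; it is a mislabelled
  background/supporting reference. Same-day publication is kept — the
  boundary is deliberately strict, and links whose dates cannot be
  resolved are kept and flagged `undatable` rather than dropped
  (failing safe preserves recall; the report can footnote them).
- Registry record version counts proxy study-team activity: a record
  updated many times belongs to an actively managed (often
  higher-impact) study, and a never-updated record with no links is a
  "zero-information" study.

## Parameters that matter

| parameter | default | units | role |
|---|---|---|---|
| `condition_keywords` | COVID-19 set | lowercase substrings | cohort membership via conditions/titles |
| `eligible_statuses` | recruiting, active (incl. enrolling by invitation), completed, terminated | enum | "recruiting, active, or ended" eligibility |
| `type_weight` | 1 / 0.5 / 0.25 | multiplier | result vs protocol vs editorial priority |
| `us_bonus` | 0.5 | score | focus-country site bonus (regulatory relevance; configurable to any country) |
| `update_unit`, `update_cap` | 0.01, 0.25 | score/update | record-activity term, saturating |
| `recency_scale`, `recency_weight` | 180 d, 0.25 | days, score | exponential recency decay |
| `intervention_weight` | 0.1 | score | normalized intervention-significance term |
| `min_updates` | 2 | updates beyond initial | "multiple updates" shortlist threshold (version_count ≥ 3) |
| `na_value` | 1 | phase value | weight of unphased trials in the significance score |

The keyword list is representative, not authoritative — it is
configuration, and any condition can be surveilled by swapping it.

## Design choices where the design was open

**Unphased-trial weight in the significance score.** Published
per-phase count/score tables are exactly reproduced when unphased
(N/A-phase) trials contribute `1 + 0.01·n`, the same value as phase 1;
the weight was *derived* by that reconstruction, not stated anywhere,
so it is a documented, configurable default. (One published prose
figure — a "highest intervention score" of 8.301 — contradicts the same
source's own table value of 12.2 for identical counts; the formula that
reproduces the full table is implemented.)

**Attention-score functional form.** Sources describing
attention-style ranking state the *drivers* (recency, phase,
intervention significance, update count, US site, article type) but
not the formula. We ship an explicit parameterization — article-type
multiplier times the sum of a phase term, a US bonus, a capped linear
update term, an exponential recency term, and a normalized intervention
term — with every weight in configuration and the per-component
breakdown returned with each score, so any user can re-weight or zero
terms. Published attention-score *values* are therefore not
reproduction targets; the score's monotonicity properties are what the
tests pin down.

**Date precision.** Registry and PubMed dates arrive at day, month, or
year precision. Month-precision dates impute to day 1, year-precision
to January 1, and the precision flag travels with the value so interval
arithmetic can be footnoted. No arithmetic ever consumes a missing
date: comparisons guard on the missing flag and route to
`undetermined`/`undatable` outcomes instead.

**Rounding.** Printed percentages use half-up rounding to one decimal
(`round_half_up()`), not R's round-half-to-even: 419/2669 → 15.7,
40/290 → 13.8. Significance scores are stored at full precision and
printed to two decimals.

**Tie-breaking.** Ranking ties break by publication date descending
(newer first), then PMID ascending — invented purely for determinism,
so ranked lists are reproducible across runs and platforms.

**Registration timing boundaries.** Same-day registration counts as
`prior` (≤ on the start-date side); `after` requires a completion date
(primary preferred, else overall) strictly before first posting, and
can be decided even when the start date is missing.

**Version counts.** Neither public registry dialect carries a per-study
version count, so the parser accepts an optional `versionCount` /
`<version_count>` element (our export extension, emitted by the
synthetic generator) and defaults to 1. The package consumes the count
as provided metadata; it does not crawl registry version history.

**Termination lexicon.** Free-text `why_stopped` values map to
categories by lowercase substring rules applied in fixed order
(recruitment → safety → futility → external results); the lexicon ships
as editable configuration because sites accumulate their own phrasings.

## The synthetic-corpus generator

`generate_corpus()` exists so every stage is testable offline with
known answers. It emulates: the two link routes with configurable
overlap (`p_both ≤ min(p_registry, p_abstract)` enforced before
generation), backdated registry references (publication 30–400 days
before trial start), the protocol/result/editorial article mix,
month-to-multi-year completion horizons, update-count variation, and
truncated-normal publication lags (default mean 149 days, sd 40,
minimum 1 day — result articles do not precede their trial unless
planted as misclassified). Default rates mirror a large condition
cohort observed mid-pandemic: ~13% registry-linked and ~16%
abstract-linked trials, 2% both, ~11% vaccine-titled trials, 25% with
a US site, 17% never-updated records. Each record category draws from
its own seed-derived stream, so enlarging one study type does not
perturb another's draws, and the same seed yields byte-identical
corpora.

What it does **not** emulate — and what passing tests therefore do not
show about real data: free-text messiness beyond dose/punctuation/
synonym variation, sponsor–publication covariance, non-NCT registries,
multi-trial articles, and the real prevalence of mislabelled
references (it plants them at a configurable rate; real prevalence is
an empirical matter). Recovery tests demonstrate correctness of the
*mechanics*, not real-world recall.

`make_reference_corpus()` is a fixed, RNG-free corpus whose
per-intervention phase profiles equal well-known published surveillance
values (e.g. hydroxychloroquine 3/36/54/16/11 across phases 1–4 plus
unphased; a tocilizumab profile with 12 phase-3 trials; the mRNA-1273
vaccine at 3/2/4), with one phase-3 trial per intervention recorded as
phase 2/3 to exercise combined-phase promotion end to end.

## Problem sizes

The shipped tests run a shared 200-study corpus for module-level
checks, a 2000-study corpus with ~30 planted backdated references for
the end-to-end recovery check, a 700-trial high-link-rate corpus
(~400 links) for publication-lag parameter recovery (planted mean 149
days recovered within ±4), and a 1000-item random list for the
ranking-oracle comparison — sizes chosen so each statistical check has
adequate resolution while the full suite stays fast.

## Known limitations

- Unlinked result articles are invisible; this is inherent to
  structured-link surveillance, not fixable by configuration.
- One registry (ClinicalTrials.gov) and one bibliographic source
  (PubMed); EUCTR/ChiCTR accessions in secondary identifiers are
  ignored.
- Intervention normalization is rule-based; distinct strings for the
  same agent beyond the synonym map remain distinct interventions.
- The attention score is a prioritization heuristic, not a validated
  impact measure; its weights encode editorial judgments (e.g. the US
  site bonus reflects regulatory mandates tied to US sites and can be
  repointed at any country).

## A worked pass

```{r, eval = FALSE}
library(trialpubs)
spec <- corpus_spec(n_interventional = 300, n_observational = 80,
                    n_registry = 20, seed = 7)
corpus <- generate_corpus(spec, dir = "corpus_out")   # writes both dialects
studies <- read_study_records("corpus_out/studies_api.json", "api_v2_json")
articles <- read_article_records("corpus_out/articles.xml")
res <- run_pipeline(studies, articles, as_of = as.Date("2021-08-15"),
                    out_dir = "surveillance_out")
res$summary
head(res$shortlist)
```
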