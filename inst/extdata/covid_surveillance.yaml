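# Example surveillance configuration (COVID-19 defaults).
# Any key may be omitted; package defaults then apply.
project: trialpubs
cohort:
  condition_keywords: [covid, covid-19, sars-cov-2, 2019-ncov, sars-cov2, novel coronavirus]
  eligible_statuses: [recruiting, active_not_recruiting, enrolling_by_invitation, completed, terminated]
  vaccine_title_keyword: vaccine
  focus_country: United States
weights:
  type_weight: {result: 1.0, protocol: 0.5, other: 0.25}
  us_bonus: 0.5
  update_unit: 0.01
  update_cap: 0.25
  recency_scale: 180
  recency_weight: 0.25
  intervention_weight: 0.1
min_updates: 2
synonym_file: intervention_synonyms.csv
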