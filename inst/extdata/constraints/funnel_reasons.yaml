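slice: funnel_reasons
provenance: non-exclusive ineligibility reasons with the 176-record
  ineligible denominator used by the results percentages
fields: [complete, no_substance, age_bad, outside, county_fail, drug_fail]
constraints:
- name: total_entries
  pred: 'TRUE'
  count: 528
  where: 'reported funnel: total screening entries'
- name: incomplete
  pred: '!complete'
  count: 118
  where: 'reported funnel: incomplete entries'
- name: ineligible
  pred: 'complete & (no_substance | age_bad | outside | county_fail | drug_fail)'
  count: 176
  where: 'reported: ineligible denominator (410 - 234)'
- name: no_substance
  pred: 'complete & no_substance'
  count: 116
  where: 'reported: 65.9% of ineligible reported no recent opioid use'
- name: age_out_of_range
  pred: 'complete & age_bad'
  count: 72
  where: 'reported: 41% outside the eligible age range'
- name: outside_area
  pred: 'complete & outside'
  count: 23
  where: 'reported: 13.1% living outside the study area'
- name: quiz_failures
  pred: 'complete & (county_fail | drug_fail)'
  count: 12
  where: 'reported: 6.8% failed the county and/or drug quiz'
- name: county_quiz_failures
  pred: 'complete & county_fail'
  count: 5
  where: 'reported: county quiz failures (n=5)'
- name: drug_quiz_failures
  pred: 'complete & drug_fail'
  count: 7
  where: 'reported: drug quiz failures (n=7)'
- name: no_reasons_when_incomplete
  pred: '!complete & (no_substance | age_bad | outside | county_fail | drug_fail)'
  count: 0
  where: 'structural: reasons only defined for complete entries'
- name: no_drug_quiz_without_substance
  pred: 'no_substance & drug_fail'
  count: 0
  where: 'structural: no drug quiz when nothing reported'
- name: no_scored_county_quiz_outside
  pred: 'outside & county_fail'
  count: 0
  where: 'structural: generic quiz outside the area is unscored'
- name: overlap_no_substance_age
  pred: 'complete & no_substance & age_bad'
  count: 47
  where: 'derived: overlap realizing the ineligible union of 176'
- name: overlap_no_substance_outside
  pred: 'complete & no_substance & outside'
  count: 0
  where: 'derived: overlap allocation'
- name: overlap_age_outside
  pred: 'complete & age_bad & outside'
  count: 0
  where: 'derived: overlap allocation'
- name: quiz_fail_report_disjoint
  pred: '(county_fail | drug_fail) & (no_substance | age_bad | outside)'
  count: 0
  where: 'derived: the 12 quiz failures met the report criteria'
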