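slice: funnel_fig2
provenance: screening funnel counts (entries, completeness, report-based
  eligibility, quiz failures among the otherwise eligible)
fields: [complete, no_substance, age_bad, outside, county_fail, drug_fail]
constraints:
- name: total_entries
  pred: 'TRUE'
  count: 528
  where: 'reported funnel: total screening entries'
- name: incomplete
  pred: '!complete'
  count: 118
  where: 'reported funnel: incomplete entries (22.3%)'
- name: report_ineligible
  pred: 'complete & (no_substance | age_bad | outside)'
  count: 161
  where: 'reported funnel: ineligible on self-report criteria (39.3% of 410)'
- name: no_substance
  pred: 'complete & no_substance'
  count: 116
  where: 'reported: no recent opioid use reported'
- name: age_out_of_range
  pred: 'complete & age_bad'
  count: 72
  where: 'reported: outside the 18-35 age range'
- name: outside_area
  pred: 'complete & outside'
  count: 23
  where: 'reported: living outside the study area'
- name: quiz_failures
  pred: 'complete & !(no_substance | age_bad | outside) & (county_fail | drug_fail)'
  count: 15
  where: 'reported funnel: 249 met report criteria, 234 passed the quizzes'
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
  count: 50
  where: 'derived: overlap realizing the report-ineligible union of 161'
- name: overlap_no_substance_outside
  pred: 'complete & no_substance & outside'
  count: 0
  where: 'derived: overlap allocation'
- name: overlap_age_outside
  pred: 'complete & age_bad & outside'
  count: 0
  where: 'derived: overlap allocation'
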