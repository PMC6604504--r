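slice: udt_heroin_reporters
provenance: 21 tested participants reporting heroin in the past 24 h
fields: [opi, bup, oxy]
constraints:
- name: tested
  pred: 'TRUE'
  count: 21
  where: 'concordance table: heroin row n=21'
- name: opiates_positive
  pred: 'opi'
  count: 8
  where: 'concordance table: 8 (38%) opiate-panel positive'
- name: bup_positive
  pred: 'bup'
  count: 8
  where: 'derived: buprenorphine positives outside the bup reporters'
- name: opi_bup_overlap
  pred: 'opi & bup'
  count: 1
  where: 'derived: overlap making the any-opioid union 25'
- name: oxy_positive
  pred: 'oxy'
  count: 0
  where: 'derived: the single oxycodone positive is a Percocet reporter'
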