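slice: udt_bup_reporters
provenance: 9 tested participants reporting buprenorphine in the past 24 h
fields: [opi, bup, oxy]
constraints:
- name: tested
  pred: 'TRUE'
  count: 9
  where: 'concordance table: buprenorphine row n=9'
- name: bup_positive
  pred: 'bup'
  count: 8
  where: 'concordance table: 8 (89%) buprenorphine-panel positive'
- name: opi_positive
  pred: 'opi'
  count: 1
  where: 'derived: the ninth opiate positive of the panel table'
- name: opi_bup_overlap
  pred: 'opi & bup'
  count: 1
  where: 'derived: overlap making the any-opioid union 25'
- name: oxy_positive
  pred: 'oxy'
  count: 0
  where: 'derived: the single oxycodone positive is a Percocet reporter'
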