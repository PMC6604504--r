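slice: udt_percocet_reporters
provenance: 4 tested participants reporting Percocet in the past 24 h
fields: [opi, bup, oxy]
constraints:
- name: tested
  pred: 'TRUE'
  count: 4
  where: 'concordance table: Percocet row n=4'
- name: oxy_positive
  pred: 'oxy'
  count: 1
  where: 'concordance table: 1 (25%) oxycodone-panel positive'
- name: bup_positive
  pred: 'bup'
  count: 1
  where: 'derived: 17th buprenorphine positive of the panel table'
- name: oxy_bup_overlap
  pred: 'oxy & bup'
  count: 0
  where: 'derived: disjoint, keeping the any-opioid union at 25'
- name: opi_positive
  pred: 'opi'
  count: 0
  where: 'derived: opiate positives are heroin/bup reporters'
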