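slice: udt_other
provenance: remaining positive panels over the 34 tested participants
fields: [marijuana, benzo, pcp]
constraints:
- name: tested
  pred: 'TRUE'
  count: 34
  where: 'panel table: N=34'
- name: marijuana_positive
  pred: 'marijuana'
  count: 18
  where: 'panel table: marijuana 18 (53%)'
- name: benzo_positive
  pred: 'benzo'
  count: 2
  where: 'panel table: benzodiazepines 2 (6%)'
- name: pcp_positive
  pred: 'pcp'
  count: 1
  where: 'panel table: phencyclidine 1 (3%)'
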