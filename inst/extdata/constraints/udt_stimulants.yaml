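slice: udt_stimulants
provenance: stimulant panels over the 34 tested participants
fields: [meth, amph, coc]
constraints:
- name: tested
  pred: 'TRUE'
  count: 34
  where: 'panel table: N=34'
- name: meth_positive
  pred: 'meth'
  count: 21
  where: 'panel table: methamphetamine 21 (62%)'
- name: amph_positive
  pred: 'amph'
  count: 21
  where: 'panel table: amphetamine 21 (62%)'
- name: cocaine_positive
  pred: 'coc'
  count: 3
  where: 'panel table: cocaine 3 (9%)'
- name: any_stimulant
  pred: 'meth | amph | coc'
  count: 22
  where: 'panel table: any stimulant 22 (65%)'
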