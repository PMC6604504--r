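slice: bup_strips
provenance: buprenorphine-strip quiz; all passed
fields: [dose, image]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 9
  where: 'reported: 9 quizzed on buprenorphine strips'
- name: passers
  pred: 'dose | image'
  count: 9
  where: 'reported: all passed'
- name: both_correct
  pred: 'dose & image'
  count: 8
  where: 'reported: 89% (8/9) answered both correctly'
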