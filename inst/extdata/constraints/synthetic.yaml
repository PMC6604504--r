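slice: synthetic
provenance: synthetic-opioid reporters auto-pass on completion; count
  chosen so the combined drug-quiz population totals 294 with 285 passers
fields: [quizzed]
constraints:
- name: total
  pred: 'TRUE'
  count: 3
  where: 'derived: 294 quizzed - 291 in the scored drug groups'
- name: quizzed
  pred: 'quizzed'
  count: 3
  where: 'derived: all completed the unscored synthetic questions'
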