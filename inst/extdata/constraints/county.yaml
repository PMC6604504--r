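slice: county
provenance: county-quiz score distribution among eligible-county
  reporters; pass = 3 of 5
fields: [i1, i2, i3, i4, i5]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 387
  where: 'reported: 387 reported an eligible county; 98.4% passed'
- name: score_5
  pred: '(i1 + i2 + i3 + i4 + i5) == 5'
  count: 347
  where: 'reported: 91.1% of 381 passers answered all 5 correctly'
- name: score_4
  pred: '(i1 + i2 + i3 + i4 + i5) == 4'
  count: 30
  where: 'derived: passer mean score 4.9 with 347 perfect scores'
- name: score_3
  pred: '(i1 + i2 + i3 + i4 + i5) == 3'
  count: 4
  where: 'derived: passer mean score 4.9 with 347 perfect scores'
- name: failures
  pred: '(i1 + i2 + i3 + i4 + i5) <= 2'
  count: 6
  where: 'reported: 6 of 387 failed the county quiz'
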