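slice: bup_pills
provenance: buprenorphine-pill quiz; the printed dose/image/both passer
  marginals are jointly infeasible, so the both-correct count is left to
  emerge (55) rather than pinned to the printed 53
fields: [dose, image]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 66
  where: 'reported: 66 quizzed on buprenorphine pills'
- name: failures
  pred: '!(dose | image)'
  count: 3
  where: 'reported: 3 answered both incorrectly and failed'
- name: dose_correct
  pred: 'dose'
  count: 60
  where: 'reported: 95% of 63 passers answered the dose correctly'
- name: image_correct
  pred: 'image'
  count: 58
  where: 'reported: 92% of 63 passers answered the image correctly'
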