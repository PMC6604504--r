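slice: methadone
provenance: methadone quiz; one incorrect pill-dose answer, no failures
fields: [dose, image]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 4
  where: 'reported: 4 quizzed on methadone'
- name: dose_correct
  pred: 'dose'
  count: 3
  where: 'reported: one methadone pill dose answered incorrectly'
- name: image_correct
  pred: 'image'
  count: 4
  where: 'reported: no other incorrect methadone answers'
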