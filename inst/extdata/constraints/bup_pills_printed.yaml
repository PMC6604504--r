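slice: bup_pills_printed
provenance: buprenorphine-pill passer marginals exactly as printed;
  arithmetically infeasible (53 + 7 + 5 = 65 > 63), kept as the
  infeasibility-detection case
fields: [dose, image]
constraints:
- name: passers
  pred: 'TRUE'
  count: 63
  where: 'reported: 63 passed the buprenorphine-pill quiz'
- name: dose_correct
  pred: 'dose'
  count: 60
  where: 'reported: 95% (60/63) dose correct'
- name: image_correct
  pred: 'image'
  count: 58
  where: 'reported: 92% (58/63) image correct'
- name: both_correct
  pred: 'dose & image'
  count: 53
  where: 'reported: 84% (53/63) both correct'
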