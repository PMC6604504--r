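slice: prescription
provenance: prescription-opioid drug-quiz accuracies; pass = dose or
  image correct
fields: [dose, image, percocet, norco, tylox]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 40
  where: 'reported: 38 passers + 2 failures'
- name: passers
  pred: 'dose | image'
  count: 38
  where: 'reported: passed a prescription-opioid quiz'
- name: fail_percocet
  pred: '!(dose | image) & percocet'
  count: 1
  where: 'reported: one failure on the Percocet quiz'
- name: fail_tylox
  pred: '!(dose | image) & tylox'
  count: 1
  where: 'reported: one failure on the Tylox quiz'
- name: dose_correct_passers
  pred: '(dose | image) & dose'
  count: 36
  where: 'reported: 95% of passers answered the dose correctly'
- name: image_correct_passers
  pred: '(dose | image) & image'
  count: 31
  where: 'reported: 82% of passers selected the correct image'
- name: image_wrong_percocet
  pred: '(dose | image) & !image & percocet'
  count: 6
  where: 'reported: six incorrect images were for Percocet'
- name: image_wrong_norco
  pred: '(dose | image) & !image & norco'
  count: 1
  where: 'reported: one incorrect image was for Norco'
- name: dose_wrong_percocet
  pred: '(dose | image) & !dose & percocet'
  count: 2
  where: 'reported: both incorrect dose responses were for Percocet'
- name: drug_flags_exclusive_pn
  pred: 'percocet & norco'
  count: 0
  where: 'structural: one quizzed drug per record'
- name: drug_flags_exclusive_pt
  pred: 'percocet & tylox'
  count: 0
  where: 'structural: one quizzed drug per record'
- name: drug_flags_exclusive_nt
  pred: 'norco & tylox'
  count: 0
  where: 'structural: one quizzed drug per record'
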