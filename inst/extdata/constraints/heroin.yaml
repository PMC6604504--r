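slice: heroin
provenance: heroin drug-quiz accuracies; pass = cap size or street price
  correct; image recorded but unscored
fields: [cap, price, image]
constraints:
- name: quizzed
  pred: 'TRUE'
  count: 172
  where: 'reported: 168 passers + 4 failures'
- name: passers
  pred: 'cap | price'
  count: 168
  where: 'reported: passed the heroin quiz'
- name: cap_and_price
  pred: 'cap & price'
  count: 154
  where: 'reported: 91.7% of passers answered both correctly'
- name: cap_correct
  pred: 'cap'
  count: 159
  where: 'reported: 94.6% of passers answered cap size correctly'
- name: price_correct
  pred: 'price'
  count: 163
  where: 'reported: 97.0% of passers answered street price correctly'
- name: image_correct_passers
  pred: 'image & (cap | price)'
  count: 167
  where: 'reported: 99.4% of passers recognized powdered heroin'
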