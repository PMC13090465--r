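# Swanson, Nolan and Pelham Scale (SNAP-IV), 26 items, 0-to-3 Likert.
# Four-factor structure with hyperactivity and impulsivity separated.
name: SNAP-IV
full_name: Swanson, Nolan and Pelham Scale
rater: [caregiver]
age_range: [6, 18]
response:
  n_categories: 4
items: [item1, item2, item3, item4, item5, item6, item7, item8, item9,
        item10, item11, item12, item13, item14, item15, item16, item17,
        item18, item19, item20, item21, item22, item23, item24, item25,
        item26]
subscales:
  inattention: [item1, item2, item3, item4, item5, item6, item7, item8, item9]
  hyperactivity: [item10, item11, item12, item13, item14]
  impulsivity: [item15, item16, item17, item18]
  oppositionality: [item19, item20, item21, item22, item23, item24, item25, item26]
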