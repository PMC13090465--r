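# Pediatric Symptom Checklist, 17-item short version.
# 0-to-2 Likert responses; three-factor structure.
name: PSC-17
full_name: Pediatric Symptom Checklist - Shortened Version
rater: [caregiver, self]
age_range: [3, 18]
response:
  n_categories: 3
items: [item1, item2, item3, item4, item5, item6, item7, item8, item9,
        item10, item11, item12, item13, item14, item15, item16, item17]
subscales:
  externalizing: [item4, item5, item8, item10, item12, item14, item16]
  internalizing: [item2, item6, item9, item11, item15]
  attention: [item1, item3, item7, item13, item17]
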