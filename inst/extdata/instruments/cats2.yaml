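# Child and Adolescent Trauma Screen-2 (CATS-2), PTSD symptom section.
# 20 items, 0-to-3 Likert, unidimensional (DSM-5 structure). The 15-item
# trauma-exposure checklist preceding the symptom section is not scored
# and is not part of this structure. Items are labelled sequentially.
name: CATS-2
full_name: Child and Adolescent Trauma Screen-2 (symptom section)
rater: [self, caregiver]
age_range: [6, 18]
response:
  n_categories: 4
items: [item1, item2, item3, item4, item5, item6, item7, item8, item9,
        item10, item11, item12, item13, item14, item15, item16, item17,
        item18, item19, item20]
subscales:
  ptsd_symptoms: [item1, item2, item3, item4, item5, item6, item7, item8,
                  item9, item10, item11, item12, item13, item14, item15,
                  item16, item17, item18, item19, item20]
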