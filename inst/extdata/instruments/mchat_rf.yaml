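# Modified Checklist for Autism in Toddlers - Revised (MCHAT-R/F).
# 20 yes/no items, unidimensional.
name: MCHAT-R/F
full_name: Modified Checklist for Autism in Toddlers - Revised
rater: [caregiver]
age_range: [1, 3]
response:
  n_categories: 2
items: [item1, item2, item3, item4, item5, item6, item7, item8, item9,
        item10, item11, item12, item13, item14, item15, item16, item17,
        item18, item19, item20]
subscales:
  unidimensional: [item1, item2, item3, item4, item5, item6, item7, item8,
                   item9, item10, item11, item12, item13, item14, item15,
                   item16, item17, item18, item19, item20]
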