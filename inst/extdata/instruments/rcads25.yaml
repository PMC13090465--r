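# Revised Children's Anxiety and Depression Scale, 25-item short version.
# 0-to-3 Likert responses; two-factor structure (anxiety / depression).
name: RCADS-25
full_name: Revised Children's Anxiety and Depression Scale - Short Version
rater: [self, caregiver]
age_range: [6, 18]
response:
  n_categories: 4
items: [item1, item2, item3, item4, item5, item6, item7, item8, item9,
        item10, item11, item12, item13, item14, item15, item16, item17,
        item18, item19, item20, item21, item22, item23, item24, item25]
subscales:
  anxiety: [item2, item3, item5, item6, item7, item9, item11, item12,
            item14, item17, item18, item20, item22, item23, item25]
  depression: [item1, item4, item8, item10, item13, item15, item16,
               item19, item21, item24]
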