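# Child Autism Spectrum Test (CAST), 28-item two-factor version.
# Yes/no items. The original 37-item numbering is preserved as ids, so the
# 28 retained items carry labels up to item37.
name: CAST
full_name: Child Autism Spectrum Test
rater: [caregiver]
age_range: [3, 6]
response:
  n_categories: 2
items: [item1, item2, item5, item7, item8, item9, item10, item11, item13,
        item15, item16, item17, item18, item20, item21, item23, item24,
        item25, item27, item28, item29, item30, item31, item32, item34,
        item35, item36, item37]
subscales:
  social_contact: [item1, item2, item5, item8, item10, item11, item13,
                   item15, item16, item17, item21, item23, item24, item27,
                   item31, item35]
  inflexible_repetitive: [item7, item9, item18, item20, item25, item28,
                          item29, item30, item32, item34, item36, item37]
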