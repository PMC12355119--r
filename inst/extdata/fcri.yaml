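# Fear of Cancer Recurrence Inventory: 42 items, 0-4 Likert, item 13
# reverse-scored. Item-to-dimension layout follows the instrument's
# standard structure; edit this file to match a local adaptation.
# Subscale order fixes the F1..F7 node labels used by the network.
name: FCRI
range: [0, 4]
items: [fcri_1, fcri_2, fcri_3, fcri_4, fcri_5, fcri_6, fcri_7, fcri_8,
        fcri_9, fcri_10, fcri_11, fcri_12, fcri_13, fcri_14, fcri_15,
        fcri_16, fcri_17, fcri_18, fcri_19, fcri_20, fcri_21, fcri_22,
        fcri_23, fcri_24, fcri_25, fcri_26, fcri_27, fcri_28, fcri_29,
        fcri_30, fcri_31, fcri_32, fcri_33, fcri_34, fcri_35, fcri_36,
        fcri_37, fcri_38, fcri_39, fcri_40, fcri_41, fcri_42]
reverse: [fcri_13]
subscales:
  triggers: [fcri_1, fcri_2, fcri_3, fcri_4, fcri_5, fcri_6, fcri_7, fcri_8]
  severity: [fcri_9, fcri_10, fcri_11, fcri_12, fcri_13, fcri_14, fcri_15,
             fcri_16, fcri_17]
  psychological_distress: [fcri_18, fcri_19, fcri_20, fcri_21]
  functioning_impairments: [fcri_31, fcri_32, fcri_33, fcri_34, fcri_35,
                            fcri_36]
  insight: [fcri_37, fcri_38, fcri_39]
  reassurance: [fcri_40, fcri_41, fcri_42]
  coping_strategies: [fcri_22, fcri_23, fcri_24, fcri_25, fcri_26, fcri_27,
                      fcri_28, fcri_29, fcri_30]
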