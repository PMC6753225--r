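battery: AIBL
tests:
  - name: cvlt_dr
    label: CVLT delayed recall
    functions: [ATT, EM1, EM2, EM3]
    response: quartile
    orientation: higher
  - name: cvlt_wr
    label: CVLT word recognition
    functions: [ATT, EM1]
    response: quartile
    orientation: higher
  - name: cvlt_lists1to5
    label: CVLT lists 1-5
    functions: [ATT, EM1, EM2]
    response: quartile
    orientation: higher
  - name: cvlt_listb
    label: CVLT list B
    functions: [ATT, EM1, EM2]
    response: quartile
    orientation: higher
  - name: boston
    label: Boston naming test
    functions: [ATT, VF]
    response: quartile
    orientation: higher
  - name: category_fluency
    label: Category fluency (animals and boy's names)
    functions: [ATT, VF, CF]
    response: quartile
    orientation: higher
  - name: category_switching
    label: Category switching
    functions: [ATT, VF, CF]
    response: quartile
    orientation: higher
  - name: stroop_words
    label: Stroop words
    functions: [ATT]
    response: timed
    orientation: lower
  - name: stroop_colors
    label: Stroop colors
    functions: [ATT, CF]
    response: timed
    orientation: lower
  - name: cogstate_detection
    label: CogState detection
    functions: [ATT, PS]
    response: timed
    orientation: lower
  - name: cogstate_identification
    label: CogState identification
    functions: [ATT, PS]
    response: timed
    orientation: lower
  - name: cogstate_oneback
    label: CogState one back
    functions: [ATT, EM1]
    response: quartile
    orientation: higher
  - name: cogstate_onecard
    label: CogState one card learning
    functions: [ATT, EM1, EM2, PS]
    response: quartile
    orientation: higher
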