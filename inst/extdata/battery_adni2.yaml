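battery: ADNI2
tests:
  - name: adas_dr
    label: ADAS delayed recall subscale
    functions: [ATT, EM1, EM2, EM3]
    response: quartile
    orientation: lower
  - name: adas_wr
    label: ADAS word recognition subscale
    functions: [ATT, EM1]
    response: quartile
    orientation: lower
  - name: avlt_list6
    label: AVLT list 6
    functions: [ATT, EM1, EM2, EM3]
    response: quartile
    orientation: higher
  - name: avlt_listb
    label: AVLT list B
    functions: [ATT, EM1, EM2]
    response: quartile
    orientation: higher
  - name: boston
    label: Boston naming test
    functions: [ATT, VF]
    response: quartile
    orientation: higher
  - name: category_fluency
    label: Category fluency (animals and vegetables)
    functions: [ATT, VF, CF]
    response: quartile
    orientation: higher
  - name: adas_nc
    label: ADAS number cancellation
    functions: [ATT]
    response: quartile
    orientation: lower
  - name: trails_a
    label: Trail making test A
    functions: [ATT, PS]
    response: timed
    orientation: lower
  - name: trails_b
    label: Trail making test B
    functions: [ATT, CF, PS]
    response: timed
    orientation: lower
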