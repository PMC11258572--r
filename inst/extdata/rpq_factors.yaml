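# Three-factor structure of the 16-item Rivermead post-concussion symptoms
# questionnaire. Item order follows the standard instrument. Factor
# membership is data, not code: edit here to explore alternative structures.
# Light sensitivity and double vision are carried under the somatic factor.
items:
  - {index: 1,  label: headaches,                     factor: somatic}
  - {index: 2,  label: dizziness,                     factor: somatic}
  - {index: 3,  label: nausea_vomiting,               factor: somatic}
  - {index: 4,  label: noise_sensitivity,             factor: somatic}
  - {index: 5,  label: sleep_disturbance,             factor: somatic}
  - {index: 6,  label: fatigue,                       factor: somatic}
  - {index: 7,  label: irritability,                  factor: emotional}
  - {index: 8,  label: depression_tearfulness,        factor: emotional}
  - {index: 9,  label: frustration_impatience,        factor: emotional}
  - {index: 10, label: forgetfulness_poor_memory,     factor: cognitive}
  - {index: 11, label: poor_concentration,            factor: cognitive}
  - {index: 12, label: taking_longer_to_think,        factor: cognitive}
  - {index: 13, label: blurred_vision,                factor: somatic}
  - {index: 14, label: light_sensitivity,             factor: somatic}
  - {index: 15, label: double_vision,                 factor: somatic}
  - {index: 16, label: restlessness,                  factor: emotional}
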