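# SYNTHETIC placeholder norms for the six BTACT subtests. The published
# normative means/SDs (MIDUS II cognitive project) are not redistributed
# here; these values are plausible stand-ins for simulation and testing and
# are NOT authoritative for scoring real participants. Replace with licensed
# norms for clinical use.
subtests:
  - {name: immediate_word_recall, mean: 9.5,  sd: 2.4}
  - {name: delayed_word_recall,   mean: 6.0,  sd: 2.6}
  - {name: digits_backward,       mean: 5.2,  sd: 1.5}
  - {name: category_fluency,      mean: 19.0, sd: 5.5}
  - {name: number_series,         mean: 2.6,  sd: 1.4}
  - {name: backward_counting,     mean: 37.0, sd: 9.5}
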