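# Default developmental age-interval scheme (postnatal years; prenatal
# ages negative, birth fixed at 38 weeks postconception).
intervals:
  - label: I-1
    lower: -0.5384615384615384   # 10 weeks postconception
    upper: 0                     # birth
  - label: I-2
    lower: 0
    upper: 6
  - label: I-3
    lower: 6
    upper: 40
  - label: I-4
    lower: 40
    upper: .inf
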