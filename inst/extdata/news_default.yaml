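# Default NEWS band configuration: the standard five-parameter NEWS cutoffs
# (Royal College of Physicians, 2012 aggregate scale), written in the
# package's half-open [lower, upper) convention. Published inclusive upper
# limits ("<= x") become upper = x + one unit of the parameter's printed
# resolution (1 for hr/rr/sbp/spo2, 0.1 for temp).
tool: NEWS
units:
  hr: beats/min
  spo2: percent
  rr: breaths/min
  sbp: mmHg
  temp: degC
# aggregate-score rules: total >= high_total (or any single score of 3, the
# "Red score") escalates to HIGH; totals inside medium_total are MEDIUM.
aggregate:
  medium_total: [5, 6]
  high_total: 7
bands:
  hr:
    - {lower: -inf, upper: 41, score: 3}   # <= 40
    - {lower: 41, upper: 51, score: 1}     # 41-50
    - {lower: 51, upper: 91, score: 0}     # 51-90
    - {lower: 91, upper: 111, score: 1}    # 91-110
    - {lower: 111, upper: 131, score: 2}   # 111-130
    - {lower: 131, upper: inf, score: 3}   # >= 131
  spo2:
    - {lower: -inf, upper: 92, score: 3}   # <= 91
    - {lower: 92, upper: 94, score: 2}     # 92-93
    - {lower: 94, upper: 96, score: 1}     # 94-95
    - {lower: 96, upper: inf, score: 0}    # >= 96
  rr:
    - {lower: -inf, upper: 9, score: 3}    # <= 8
    - {lower: 9, upper: 12, score: 1}      # 9-11
    - {lower: 12, upper: 21, score: 0}     # 12-20
    - {lower: 21, upper: 25, score: 2}     # 21-24
    - {lower: 25, upper: inf, score: 3}    # >= 25
  sbp:
    - {lower: -inf, upper: 91, score: 3}   # <= 90
    - {lower: 91, upper: 101, score: 2}    # 91-100
    - {lower: 101, upper: 111, score: 1}   # 101-110
    - {lower: 111, upper: 220, score: 0}   # 111-219
    - {lower: 220, upper: inf, score: 3}   # >= 220
  temp:
    - {lower: -inf, upper: 35.1, score: 3} # <= 35.0
    - {lower: 35.1, upper: 36.1, score: 1} # 35.1-36.0
    - {lower: 36.1, upper: 38.1, score: 0} # 36.1-38.0
    - {lower: 38.1, upper: 39.1, score: 1} # 38.1-39.0
    - {lower: 39.1, upper: inf, score: 2}  # >= 39.1
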