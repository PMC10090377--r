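# Default MPRT-WS band configuration: nine vital-sign parameters, each scored
# 0-3 over half-open [lower, upper) intervals partitioning the real line.
#
# The five parameters shared with NEWS (hr, spo2, rr, sbp, temp) reuse the
# standard NEWS cutoffs. The four hemodynamic additions (dbp, sv, co, svr)
# are SYNTHETIC defaults banded around accepted adult physiological normal
# ranges (dbp 60-90 mmHg, sv 60-100 mL, co 4-8 L/min, svr 800-1200
# dyn.s/cm^5), with grade-1/2/3 deviations widening stepwise on both sides;
# they are illustrative engineering defaults, not clinically validated
# cutoffs, and are expected to be replaced by a site-specific configuration.
tool: MPRT-WS
units:
  hr: beats/min
  spo2: percent
  rr: breaths/min
  sbp: mmHg
  dbp: mmHg
  temp: degC
  sv: mL
  co: L/min
  svr: dyn.s/cm^5
bands:
  hr:
    - {lower: -inf, upper: 41, score: 3}
    - {lower: 41, upper: 51, score: 1}
    - {lower: 51, upper: 91, score: 0}
    - {lower: 91, upper: 111, score: 1}
    - {lower: 111, upper: 131, score: 2}
    - {lower: 131, upper: inf, score: 3}
  spo2:
    - {lower: -inf, upper: 92, score: 3}
    - {lower: 92, upper: 94, score: 2}
    - {lower: 94, upper: 96, score: 1}
    - {lower: 96, upper: inf, score: 0}
  rr:
    - {lower: -inf, upper: 9, score: 3}
    - {lower: 9, upper: 12, score: 1}
    - {lower: 12, upper: 21, score: 0}
    - {lower: 21, upper: 25, score: 2}
    - {lower: 25, upper: inf, score: 3}
  sbp:
    - {lower: -inf, upper: 91, score: 3}
    - {lower: 91, upper: 101, score: 2}
    - {lower: 101, upper: 111, score: 1}
    - {lower: 111, upper: 220, score: 0}
    - {lower: 220, upper: inf, score: 3}
  temp:
    - {lower: -inf, upper: 35.1, score: 3}
    - {lower: 35.1, upper: 36.1, score: 1}
    - {lower: 36.1, upper: 38.1, score: 0}
    - {lower: 38.1, upper: 39.1, score: 1}
    - {lower: 39.1, upper: inf, score: 2}
  dbp:
    - {lower: -inf, upper: 40, score: 3}
    - {lower: 40, upper: 50, score: 2}
    - {lower: 50, upper: 60, score: 1}
    - {lower: 60, upper: 91, score: 0}
    - {lower: 91, upper: 101, score: 1}
    - {lower: 101, upper: 111, score: 2}
    - {lower: 111, upper: inf, score: 3}
  sv:
    - {lower: -inf, upper: 30, score: 3}
    - {lower: 30, upper: 45, score: 2}
    - {lower: 45, upper: 60, score: 1}
    - {lower: 60, upper: 101, score: 0}
    - {lower: 101, upper: 121, score: 1}
    - {lower: 121, upper: 141, score: 2}
    - {lower: 141, upper: inf, score: 3}
  co:
    - {lower: -inf, upper: 2.0, score: 3}
    - {lower: 2.0, upper: 3.0, score: 2}
    - {lower: 3.0, upper: 4.0, score: 1}
    - {lower: 4.0, upper: 8.1, score: 0}
    - {lower: 8.1, upper: 10.1, score: 1}
    - {lower: 10.1, upper: 12.1, score: 2}
    - {lower: 12.1, upper: inf, score: 3}
  svr:
    - {lower: -inf, upper: 400, score: 3}
    - {lower: 400, upper: 600, score: 2}
    - {lower: 600, upper: 800, score: 1}
    - {lower: 800, upper: 1201, score: 0}
    - {lower: 1201, upper: 1601, score: 1}
    - {lower: 1601, upper: 2001, score: 2}
    - {lower: 2001, upper: inf, score: 3}
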