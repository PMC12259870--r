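# Classification thresholds for the corrosion/scaling indices. Editable so
# alternative threshold conventions can be applied without code changes.
lsi:
  balanced_at: 0          # < 0 corrosive, > 0 scale-forming, = 0 balanced
rsi:
  corrosive_above: 6.8
ai:
  highly_aggressive_below: 10
  non_aggressive_above: 12
psi:
  corrosive_above: 6
ls:
  low_below: 0.8
  high_above: 1.2
csmr:
  elevated_above: 0.5
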