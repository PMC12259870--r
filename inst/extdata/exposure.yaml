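# Receptor-specific exposure constants for the USEPA-style intake model.
# ir: water ingestion rate (L/day); ef: exposure frequency (days/year);
# ed: exposure duration (years); bw: body weight (kg); sa: exposed skin
# surface area (cm2); et: bathing exposure time (h/day); cf: volume
# conversion factor (L/cm3); at_carcinogenic: lifetime averaging time
# (days); at_noncarcinogenic_literal: the tabulated non-carcinogenic
# averaging time. The package default derives the non-carcinogenic AT as
# ed * 365 days; set use_literal_at_nc: true to use the literal instead.
use_literal_at_nc: false
receptors:
  adult:
    ir: 2.2
    ef: 350
    ed: 70
    bw: 70
    sa: 18000
    et: 0.58
    cf: 1.0e-3
    at_carcinogenic: 25550
    at_noncarcinogenic_literal: 10950
  child:
    ir: 1.8
    ef: 350
    ed: 6
    bw: 15
    sa: 6600
    et: 1
    cf: 1.0e-3
    at_carcinogenic: 25550
    at_noncarcinogenic_literal: 2190
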