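# Drinking-water objectives used by the quality indices.
# Health-based WHO (2017) guideline values where they exist; conventional
# aesthetic/operational objectives otherwise. Units match the sample table
# (mg/L; ph in pH units; ec in uS/cm). direction: ceiling = value must not
# exceed the objective; floor = value must not fall below it.
guidelines:
  - {parameter: ph,   objective: 6.5,  direction: floor}
  - {parameter: ph,   objective: 8.5,  direction: ceiling}
  - {parameter: ec,   objective: 1500, direction: ceiling}
  - {parameter: tds,  objective: 1000, direction: ceiling}
  - {parameter: Ca,   objective: 75,   direction: ceiling}
  - {parameter: Mg,   objective: 50,   direction: ceiling}
  - {parameter: Na,   objective: 200,  direction: ceiling}
  - {parameter: K,    objective: 12,   direction: ceiling}
  - {parameter: Cl,   objective: 250,  direction: ceiling}
  - {parameter: SO4,  objective: 250,  direction: ceiling}
  - {parameter: NO3,  objective: 50,   direction: ceiling}
  - {parameter: Fe,   objective: 0.3,  direction: ceiling}
  - {parameter: Al,   objective: 0.2,  direction: ceiling}
  - {parameter: Mn,   objective: 0.1,  direction: ceiling}
  - {parameter: Ni,   objective: 0.07, direction: ceiling}
  - {parameter: Cu,   objective: 2,    direction: ceiling}
  - {parameter: Sr,   objective: 4,    direction: ceiling}
  - {parameter: Cd,   objective: 0.003, direction: ceiling}
  - {parameter: Cr,   objective: 0.05, direction: ceiling}
  - {parameter: Pb,   objective: 0.01, direction: ceiling}
  - {parameter: Hg,   objective: 0.006, direction: ceiling}
  - {parameter: Zn,   objective: 3,    direction: ceiling}
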