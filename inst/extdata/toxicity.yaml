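# Per-metal toxicity and exposure constants for the ten risk-assessed
# metals. rfd_oral / rfd_dermal in mg/kg/day (rfd_dermal = rfd_oral * abs);
# abs = dermal absorption fraction; kp = dermal permeability coefficient
# (cm/h); csf = cancer slope factor ((mg/kg/day)^-1), oral and dermal,
# null where the metal is not treated as a carcinogen; tr = toxic response
# factor (ecological risk); cbg = geochemical background value (ppm).
metals:
  Cd: {rfd_oral: 0.0005, rfd_dermal: 0.000025, abs: 0.05,  kp: 0.001,
       csf_oral: 6.1,  csf_dermal: 6100, tr: 30, cbg: 0.2}
  Cr: {rfd_oral: 0.003,  rfd_dermal: 0.000075, abs: 0.025, kp: 0.002,
       csf_oral: 0.5,  csf_dermal: 500,  tr: 2,  cbg: 35}
  Cu: {rfd_oral: 0.04,   rfd_dermal: 0.012,    abs: 0.3,   kp: 0.001,
       csf_oral: null, csf_dermal: null, tr: 5,  cbg: 55}
  Fe: {rfd_oral: 0.7,    rfd_dermal: 0.14,     abs: 0.2,   kp: 0.001,
       csf_oral: null, csf_dermal: null, tr: 1,  cbg: 15000}
  Hg: {rfd_oral: 0.0003, rfd_dermal: 0.000021, abs: 0.07,  kp: 0.001,
       csf_oral: null, csf_dermal: null, tr: 40, cbg: 0.8}
  Mn: {rfd_oral: 0.024,  rfd_dermal: 0.00096,  abs: 0.04,  kp: 0.001,
       csf_oral: null, csf_dermal: null, tr: 1,  cbg: 600}
  Ni: {rfd_oral: 0.02,   rfd_dermal: 0.0008,   abs: 0.04,  kp: 0.0002,
       csf_oral: null, csf_dermal: null, tr: 5,  cbg: 20}
  Pb: {rfd_oral: 0.0014, rfd_dermal: 0.00042,  abs: 0.3,   kp: 0.0001,
       csf_oral: 0.5,  csf_dermal: 500,  tr: 5,  cbg: 12.5}
  Sr: {rfd_oral: 0.6,    rfd_dermal: 0.12,     abs: 0.2,   kp: 0.001,
       csf_oral: null, csf_dermal: null, tr: 1,  cbg: 350}
  Zn: {rfd_oral: 0.3,    rfd_dermal: 0.06,     abs: 0.2,   kp: 0.0006,
       csf_oral: null, csf_dermal: null, tr: 1,  cbg: 70}
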