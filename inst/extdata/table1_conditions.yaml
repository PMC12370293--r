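# Four-condition perfusion fixture for the 1 mm x 100 um x 17 mm channel.
#
# Viscosity note: the library default for culture medium at 37 C is
# 0.00072 Pa s. This fixture pins viscosity = 1.0e-3 Pa s, the value under
# which the published condition table (peak WSS 0.14 / 0.014 Pa; channel
# delta-P 47.1 / 4.71 Pa) is internally consistent; with 0.00072 Pa s all
# shear and pressure-drop figures come out ~28% lower.
mode: hemodynamics
channel:
  width_mm: 1
  height_um: 100
  length_mm: 17
fluid:
  density: 1000
  viscosity: 1.0e-3
conditions:
  - label: "SS high only"
    flow_rate_ul_min: 13
    outlet_head_cm: 0
  - label: "SS low only"
    flow_rate_ul_min: 1.3
    outlet_head_cm: 0
  - label: "SS high+HP"
    flow_rate_ul_min: 13
    outlet_head_cm: 40
  - label: "SS low+HP"
    flow_rate_ul_min: 1.3
    outlet_head_cm: 40
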