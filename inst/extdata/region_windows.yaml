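# Calpha chemical-shift analysis windows (ppm) per labeled residue type.
# Sheet windows are open-ended below (-.inf). Boundaries shared by two
# windows belong to the higher-ppm window; gaps (e.g. Arg 53.3-54.0 ppm)
# classify as unassigned.
Met:
  helix: [55.0, 59.2]
  coil: [52.7, 54.8]
  sheet: [-.inf, 52.7]
Arg:
  helix: [56.7, 60.2]
  coil: [54.0, 56.6]
  sheet: [-.inf, 53.3]
His:
  helix: [56.0, 58.8]
  coil: [52.5, 56.0]
  sheet: [-.inf, 52.5]
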