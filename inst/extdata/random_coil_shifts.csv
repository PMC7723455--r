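# Random-coil Calpha/Cbeta reference shifts (ppm, DSS-referenced), from
# standard published random-coil compilations. Editable: compilations differ
# at the few-tenths-ppm level and the classification thresholds (+-1.4 ppm)
# are wide relative to that spread.
residue,ca_ppm,cb_ppm
Met,55.4,32.9
Arg,56.1,30.3
His,55.5,29.9
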