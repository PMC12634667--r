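# Steady oxygen field in the largest tissue geometry at the high end of
# the measured single-cell OCR distribution.
stage: oxygen
geometry: V3
socr: 6.1e-17
diffusivity: 2.0e-9
n: [40, 120, 20]
seed: 1
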