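# Burst-pressure run for the pillar-array fenestra of the cardiac device:
# 8 pillars with 8 um pores in a 708 um region, 2 um fenestration height,
# water-air interfacial properties.
stage: burst
fenestra: pillar_array
n_pillars: 8
pore_size: 8
region_length: 708
height: 2
surface_tension: 0.072
contact_angle: 66
seed: 1
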