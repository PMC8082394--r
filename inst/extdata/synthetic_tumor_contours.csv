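slice_index,area_cm2
1,0.12
2,0.45
3,0.78
4,0.81
5,0.42
6,0.22
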