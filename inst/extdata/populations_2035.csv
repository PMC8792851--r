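state,population_millions
1,59.38
2,133.78
3,149.83
4,75.09
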