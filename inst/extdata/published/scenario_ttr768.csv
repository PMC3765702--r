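arm,mean_cost,mean_qaly
sdw,7289,3.5358
gtw,7611,3.6348
dab150,8494,3.7897
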