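arm,mean_cost,mean_qaly
dab150,5217,3.7897
sdw,7289,3.5368
gtw,7749,3.5453
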