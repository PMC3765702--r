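arm,mean_cost,mean_qaly
sdw,7289,3.5358
gtw,7749,3.5453
dab150,8879,3.695
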