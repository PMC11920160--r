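sex	deaths	non_deaths
F	514	4497
M	467	4625
UNK	75	735
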