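name,n,mean_d13C,sd_d13C,mean_d15N,sd_d15N
Gastropods and Bivalves,13,-18.39,0.80,9.24,0.80
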