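name,n,mean_d13C,sd_d13C,mean_d15N,sd_d15N
Sea Anemones,10,-20.16,0.50,12.45,0.74
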