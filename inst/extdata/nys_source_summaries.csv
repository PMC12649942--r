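name,n,mean_d13C,sd_d13C,mean_d15N,sd_d15N
Small-Sized Fishes,36,-20.10,0.36,11.00,1.19
Shrimps,18,-18.24,0.99,10.58,0.52
Zooplankton,5,-24.11,0.80,7.58,0.78
POM,5,-24.41,0.76,4.53,0.20
SOM,10,-22.42,0.59,3.40,1.03
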