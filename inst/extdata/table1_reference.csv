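age_group,mean_words,sd_words,rho
4-5,4.4,1.4,0.329
6-7,5.4,1.1,0.405
8-9,7.0,1.8,0.443
10-11,9.7,2.3,0.551
adult,14.7,2.4,NA
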