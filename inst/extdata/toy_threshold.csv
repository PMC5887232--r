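source,target,weight
N1,S1,1
N2,S1,-1
N1,S2,1
S1,P,2
S2,P,-1
N2,N1,-1
P,N2,1
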