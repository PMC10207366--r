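probe,charge,lj_eps,lj_rstar
C.3,1.0,0.107,1.7
H,1.0,0.042,1.5
O.3,1.0,0.116,1.52
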