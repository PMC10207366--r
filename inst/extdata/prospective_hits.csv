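mol_id,selecting_model,hsEH,msEH,rsEH
Z211852480,logp_hb,6.9,6.2,6.3
AK-968/41927527,logp_hb,9.4,8.9,9.4
Z211761694,logp_hb,6.7,6.3,6.7
Z339843288,logp_hb,8.9,8.9,9.0
Z416144030,logp_hb,7.8,6.7,7.7
Z436130862,logp_hb,9.1,9.0,9.0
Z1499294365,logp_hb,7.7,7.1,7.4
Z237696036,logp_hb,6.7,5.3,6.4
Z353003074,logp_hb,8.2,8.0,8.3
Z29532165,qe_r3,6.3,6.4,7.4
AK-968/15603026,qe_r3,6.9,6.5,7.4
AO-476/43362680,qe_r3,5.4,4.6,4.6
AK-968/40204236,qe_r3,6.8,5.8,6.5
Z23294293,qe_r3,7.0,6.2,7.4
Z44611499,qe_r3,8.2,6.9,7.7
Z1033382608,qe_r3,6.3,5.5,6.4
Z339670416,qe_r3,7.0,5.8,6.3
Z65159029,qe_r3,5.3,4.7,5.7
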