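mol_id,experimental,qg_lj,qe_r3,logp,logp_hb
VS1_mol1,6.0,7.5,9.3,6.4,6.5
VS1_mol2,6.3,7.6,8.0,6.4,6.3
VS1_mol3,6.3,7.8,8.1,7.3,6.8
VS1_mol4,6.8,7.8,8.5,7.3,7.1
VS1_mol5,7.3,7.9,8.4,7.5,7.1
VS1_mol6,6.7,7.9,8.0,6.8,6.8
VS1_mol7,6.7,7.9,8.0,6.7,6.5
VS1_mol8,6.5,7.9,8.0,6.5,6.4
VS1_mol9,7.1,7.7,8.3,7.6,7.4
VS1_mol10,6.6,7.5,7.2,6.2,6.31
VS1_mol11,8.0,5.6,8.4,7.9,7.6
VS1_mol12,8.2,3.0,6.0,7.8,8.2
VS1_mol13,7.1,2.0,6.0,7.0,7.1
VS1_mol14,7.1,2.2,5.9,7.1,7.5
VS1_mol15,7.6,4.2,5.7,8.6,8.5
VS1_mol16,8.4,6.2,7.3,7.7,7.4
VS1_mol17,8.5,3.1,6.2,7.9,7.4
VS1_mol18,8.0,3.7,3.6,8.7,8.3
VS1_mol19,9.3,3.0,6.5,8.6,8.8
VS1_mol20,9.3,3.8,7.1,9.3,9.3
VS1_mol21,9.4,6.6,6.2,8.0,7.5
VS1_mol22,9.4,6.6,6.4,8.4,7.9
VS1_mol23,8.5,6.0,6.1,7.8,7.8
VS1_mol24,8.5,6.5,6.3,7.5,7.8
VS1_mol25,8.1,7.3,7.6,8.5,8.2
VS1_mol26,8.1,6.8,7.9,8.3,7.9
VS1_mol27,9.3,7.9,8.5,8.6,8.0
VS1_mol28,8.2,7.8,8.2,7.6,7.5
VS1_mol29,7.7,7.5,7.3,7.3,7.3
VS1_mol30,8.5,8.7,9.4,8.2,7.8
VS1_mol31,8.1,8.5,9.6,8.1,7.8
VS1_mol32,7.7,6.8,6.8,7.4,7.9
VS1_mol33,6.1,6.2,6.4,6.4,6.4
VS1_mol34,6.0,6.1,6.3,6.3,6.4
VS1_mol35,5.8,6.6,6.6,6.1,6.3
VS1_mol36,7.3,7.1,7.0,7.7,6.9
VS1_mol37,7.7,-0.7,7.1,7.5,7.6
VS1_mol38,7.5,7.8,7.7,6.5,6.4
VS1_mol39,6.5,7.1,7.2,7.3,7.5
VS1_mol40,8.3,7.9,8.0,6.8,7.5
VS1_mol41,8.5,9.1,8.2,7.2,7.7
VS1_mol42,8.1,8.8,8.2,7.4,7.8
VS1_mol43,8.3,7.8,7.6,7.5,8.1
VS1_mol44,8.2,7.5,7.5,7.6,7.8
VS1_mol45,6.8,7.2,7.4,6.3,6.6
VS1_mol46,7.9,7.4,7.5,6.4,6.9
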