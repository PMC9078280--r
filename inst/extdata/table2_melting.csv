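substance,T_fus_K,u_T_fus_K,dH_fus_kJ_per_mol,u_dH_fus_kJ_per_mol,dS_fus_kJ_per_K_mol,u_dS_fus_kJ_per_K_mol
l-alanine,608,9,22,5,0.036,0.009
glycine,569,7,21,4,0.037,0.007
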