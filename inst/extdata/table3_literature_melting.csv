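substance,T_fus_K,dH_fus_kJ_per_mol,method
l-alanine,608,22,FSC
l-alanine,608,23.7,PC-SAFT
l-alanine,539,9.24,UNIFAC
l-alanine,1191,11.09,NLF-HB
l-alanine,581.72,15.98,PC-SAFT
l-alanine,692.4,21.1,PC-SAFT
glycine,569,21,FSC
glycine,569,21.0,PC-SAFT
glycine,433,7.36,UNIFAC
glycine,535,3.5,ideal
glycine,714.3,17.54,PC-SAFT
glycine,696,13.54,NLF-HB
glycine,688,13.7,SAFT
glycine,489,21.97,PC-SAFT
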