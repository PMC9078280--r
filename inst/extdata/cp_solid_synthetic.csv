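T_K,substance,cp_J_per_gK
280,glycine,1.26
300,glycine,1.33
320,glycine,1.40
340,glycine,1.47
360,glycine,1.54
380,glycine,1.61
400,glycine,1.67
420,glycine,1.74
440,glycine,1.80
460,glycine,1.86
480,glycine,1.92
280,l-alanine,1.31
300,l-alanine,1.38
320,l-alanine,1.46
340,l-alanine,1.53
360,l-alanine,1.60
380,l-alanine,1.67
400,l-alanine,1.74
420,l-alanine,1.81
440,l-alanine,1.87
460,l-alanine,1.93
480,l-alanine,1.99
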