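trna_id	concentration_uM	codons
Phe-GAA	8.0	UUU,UUC
Leu1-CAG	42.0	CUG
Leu2-GAG	9.0	CUU,CUC
Leu3-UAG	6.0	CUA
Leu4-CAA	19.0	UUG
Leu5-UAA	11.0	UUA,UUG
Ile1-GAU	37.0	AUU,AUC
Ile2-CAU	4.0	AUA
Met-CAU	14.0	AUG
Val1-UAC	37.0	GUA,GUG,GUU
Val2-GAC	13.0	GUU,GUC
Ser1-UGA	12.0	UCU,UCA,UCG
Ser2-CGA	3.0	UCG
Ser3-GCU	7.0	AGU,AGC
Ser5-GGA	11.0	UCC,UCU
Pro1-CGG	12.0	CCG
Pro2-GGG	5.0	CCU,CCC
Pro3-UGG	6.0	CCA,CCU,CCG
Thr1-GGU	9.0	ACU,ACC
Thr2-CGU	5.0	ACG
Thr3-UGU	8.0	ACA,ACU,ACG
Ala1-UGC	38.0	GCU,GCA,GCG
Ala2-GGC	8.0	GCC,GCU
Tyr-GUA	18.0	UAU,UAC
His-GUG	7.0	CAU,CAC
Gln1-UUG	8.0	CAA
Gln2-CUG	9.0	CAG
Asn-GUU	13.0	AAU,AAC
Lys-UUU	21.0	AAA,AAG
Asp-GUC	25.0	GAU,GAC
Glu-UUC	51.0	GAA,GAG
Cys-GCA	5.0	UGU,UGC
Trp-CCA	10.0	UGG
Arg2-ICG	49.0	CGU,CGC,CGA
Arg3-CCG	4.0	CGG
Arg4-UCU	4.0	AGA,AGG
Arg5-CCU	2.0	AGG
Gly1-CCC	4.0	GGG
Gly2-UCC	12.0	GGA,GGG
Gly3-GCC	48.0	GGU,GGC
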