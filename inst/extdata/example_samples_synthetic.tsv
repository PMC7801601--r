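sample	condition	replicate
DMSO_1	DMSO	1
DMSO_2	DMSO	2
DMSO_3	DMSO	3
drugA_1	drugA	1
drugA_2	drugA	2
drugA_3	drugA	3
drugB_1	drugB	1
drugB_2	drugB	2
drugB_3	drugB	3
combo_1	combo	1
combo_2	combo	2
combo_3	combo	3
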