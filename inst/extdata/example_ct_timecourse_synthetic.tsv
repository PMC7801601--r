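gene	condition	replicate	time_h	ct
gene1	vehicle	1	0	19.9077391654042
gene1	vehicle	1	2	20.5156243834777
gene1	vehicle	1	4	21.0343122372692
gene1	vehicle	1	6	21.4869702448375
gene1	vehicle	2	0	19.9600842115088
gene1	vehicle	2	2	20.4342133578449
gene1	vehicle	2	4	20.981585701616
gene1	vehicle	2	6	21.5757440752099
gene1	combo	1	0	19.9609188896966
gene1	combo	1	2	21.176926760862
gene1	combo	1	4	22.6898055847833
gene1	combo	1	6	23.988940449568
gene1	combo	2	0	19.9587817067642
gene1	combo	2	2	21.2446428031444
gene1	combo	2	4	22.6071435740636
gene1	combo	2	6	23.9688356673935
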