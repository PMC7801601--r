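chr1	23437	24176	.	0	.
chr1	55034	55494	.	0	.
chr1	93581	93887	.	0	.
chr1	108449	109196	.	0	.
chr1	136368	137122	.	0	.
chr1	185140	185538	.	0	.
chr1	232254	232774	.	0	.
chr1	245024	245749	.	0	.
chr1	290451	290825	.	0	.
chr1	325638	326049	.	0	.
chr1	358502	359073	.	0	.
chr1	394265	394773	.	0	.
chr1	402145	402730	.	0	.
chr1	438801	439048	.	0	.
chr1	481430	481988	.	0	.
chr1	517087	517602	.	0	.
chr1	544183	544439	.	0	.
chr1	571803	572186	.	0	.
chr1	600317	600983	.	0	.
chr1	655930	656204	.	0	.
chr1	690552	691194	.	0	.
chr1	700758	701184	.	0	.
chr1	765465	765696	.	0	.
chr1	775856	776565	.	0	.
chr1	807188	807825	.	0	.
chr1	854352	855028	.	0	.
chr1	888015	888576	.	0	.
chr1	909177	909639	.	0	.
chr1	946298	946654	.	0	.
chr1	997408	997840	.	0	.
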