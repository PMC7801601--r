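gene_id	chrom	strand	tss	start	end
G01	chr1	+	20000	20000	28000
G02	chr1	-	120000	120000	128000
G03	chr1	+	220000	220000	228000
G04	chr1	-	320000	320000	328000
G05	chr1	+	420000	420000	428000
G06	chr1	-	520000	520000	528000
G07	chr1	+	620000	620000	628000
G08	chr1	-	720000	720000	728000
G09	chr1	+	820000	820000	828000
G10	chr1	-	920000	920000	928000
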