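condition	replicate	signal
vehicle	1	980.482306034619
vehicle	2	1049.55747111632
vehicle	3	1101.84573424426
vehicle	4	1044.97764973417
vehicle	5	1067.9371415974
vehicle	6	1021.60651194413
A	1	640.488187459404
A	2	583.244025265801
A	3	604.551903529223
B	1	549.572592570705
B	2	493.715573069835
B	3	501.926008491062
AB	1	322.337595149937
AB	2	283.294143610289
AB	3	312.73226501775
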