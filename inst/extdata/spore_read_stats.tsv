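sample	n_reads	percent_mapped	mean_mapped_read_length	average_variant_coverage	average_snv_coverage
INOQ_2	71940	98	138	5598	4714
INOQ_3	4456	98	105	276	226
INOQ_5	112690	98	142	9308	8707
BEG144_2	5521	95	136	436	381
BEG144_3	49936	97	156	4847	4297
BEG144_8	36707	96	144	3282	3028
BEG72_1	41944	98	155	4509	3810
BEG72_2	28258	98	156	2861	2689
BEG72_4	33927	98	152	3585	3485
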