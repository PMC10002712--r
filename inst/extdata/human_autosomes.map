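# sex-averaged autosomal genetic map skeleton (cumulative cM)
chr1	chr1_p	0
chr1	chr1_q	277.7
chr2	chr2_p	0
chr2	chr2_q	263
chr3	chr3_p	0
chr3	chr3_q	224.2
chr4	chr4_p	0
chr4	chr4_q	214.5
chr5	chr5_p	0
chr5	chr5_q	209.3
chr6	chr6_p	0
chr6	chr6_q	194.1
chr7	chr7_p	0
chr7	chr7_q	187.2
chr8	chr8_p	0
chr8	chr8_q	169.2
chr9	chr9_p	0
chr9	chr9_q	167.2
chr10	chr10_p	0
chr10	chr10_q	174.1
chr11	chr11_p	0
chr11	chr11_q	161.1
chr12	chr12_p	0
chr12	chr12_q	176
chr13	chr13_p	0
chr13	chr13_q	131.9
chr14	chr14_p	0
chr14	chr14_q	125.2
chr15	chr15_p	0
chr15	chr15_q	132.4
chr16	chr16_p	0
chr16	chr16_q	133.8
chr17	chr17_p	0
chr17	chr17_q	137.3
chr18	chr18_p	0
chr18	chr18_q	129.5
chr19	chr19_p	0
chr19	chr19_q	111.1
chr20	chr20_p	0
chr20	chr20_q	114.8
chr21	chr21_p	0
chr21	chr21_q	70.1
chr22	chr22_p	0
chr22	chr22_q	79.1
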