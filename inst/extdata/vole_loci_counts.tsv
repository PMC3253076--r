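region_id	aligned_sites	n_snps	n_indels	indel_min	indel_max
Crh	138103	1518	278	1	3054
Crhr1	72493	604	108	1	3066
Drd1A	117457	1156	235	1	773
Drd2	132468	1313	192	1	6070
Esr1	265109	2665	503	1	13667
Esr2	56409	476	100	1	1069
Nr3c1	159447	934	219	1	680
Oxt_Avp	138034	931	271	1	1091
Oxtr	151640	1353	256	1	3241
Slc6a2	127323	1288	206	1	4188
Slc6a3	100371	745	142	1	1681
Ucn2	144027	518	119	1	338
Ucn3	145967	1198	231	1	1776
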