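# Published per-isoform recovery of prohormone isoforms across six
# anemonefish de novo transcriptome assemblies. Rows are buckets of the
# number of species with complete / partial recovery; the three missing_*
# columns count isoforms missing in 0, 1-2, or 3+ species; total is the
# row sum.
complete	partial	missing_0	missing_1_2	missing_3p	total
3+	0	14	23	3	40
3+	1	27	21	1	49
3+	3+	10	11	0	21
2	0	0	0	2	2
2	3+	5	4	7	16
1	0	0	0	6	6
1	1	0	0	5	5
1	2	0	0	5	5
1	3+	5	5	6	16
0	0	0	0	6	6
0	3+	4	2	3	9
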