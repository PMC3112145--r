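gene_id	exon	size	coding
zebrafish	4	64	1
zebrafish	5	80	1
zebrafish	6	95	1
zebrafish	7	80	1
zebrafish	8	43	1
zebrafish	9	63	1
zebrafish	10	115	1
frog	4	64	1
frog	5	80	1
frog	6	95	1
frog	7	80	1
frog	8	43	1
frog	9	63	1
frog	10	115	1
chicken	4	64	1
chicken	5	80	1
chicken	6	95	1
chicken	7	80	1
chicken	8	43	1
chicken	9	63	1
chicken	10	115	1
platypus	4	64	1
platypus	5	80	1
platypus	6	95	1
platypus	7	80	1
platypus	8	43	1
platypus	9	63	1
platypus	10	115	1
opossum	4	64	1
opossum	5	80	1
opossum	6	98	1
opossum	7	80	1
opossum	8	43	1
opossum	9	63	1
opossum	10	115	1
human_D2	4	64	1
human_D2	5	80	1
human_D2	6	95	1
human_D2	7	80	1
human_D2	8	43	1
human_D2	9	63	1
human_D2	10	115	1
human_D3	4	64	1
human_D3	5	80	1
human_D3	6	92	1
human_D3	7	80	1
human_D3	8	43	1
human_D3	9	63	1
human_D3	10	115	1
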