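block	age	level	n	cases	reference	pub_or	pub_ci_low	pub_ci_high	pub_p	note
weighted	9	0-17p	494	28	1
weighted	9	18-20p	654	34	0	0.91	0.55	1.53	0.913	print_artifact_p
weighted	9	21-23p	582	29	0	0.87	0.51	1.49	0.617
weighted	9	24-31p	330	9	0	0.47	0.22	1.00	0.051
introduced	6	0-7 foods	512	24	1
introduced	6	8-9 foods	563	24	0	0.91	0.51	1.62	0.736
introduced	6	10-11 foods	618	32	0	1.11	0.65	1.92	0.705	print_artifact_ci_high
introduced	6	12-14 foods	363	20	0	1.19	0.65	2.18	0.584	print_artifact_ci_low
introduced	9	0-10 foods	465	32	1
introduced	9	11 foods	490	21	0	0.61	0.34	1.07	0.083
introduced	9	12 foods	519	24	0	0.66	0.38	1.13	0.129
introduced	9	13-14 foods	582	23	0	0.56	0.32	0.97	0.037
allergenic	6	0-2 allergenic foods	777	29	1
allergenic	6	3 allergenic foods	541	34	0				0.035	or_not_printed
allergenic	6	4 allergenic foods	442	24	0	1.48	0.85	2.58	0.165
allergenic	6	5-6 allergenic foods	296	13	0	1.19	0.61	2.31	0.619	print_artifact_or
allergenic	9	0-3 allergenic foods	548	29	1
allergenic	9	4 allergenic foods	741	38	0	0.97	0.59	1.59	0.896
allergenic	9	5 allergenic foods	575	28	0	0.92	0.54	1.56	0.747
allergenic	9	6 allergenic foods	192	5	0	0.48	0.18	1.25	0.134
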