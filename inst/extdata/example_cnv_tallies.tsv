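# Numbers of F1 mice carrying at least one confirmed de novo CNV, by sex
# stratum, CNV class (L = two or more positive first-screen probes, S =
# exactly one) and mutation kind, from the same published cohort as
# example_cnv_calls.tsv. Mice with 4 or more confirmed de novo CNVs are
# excluded by design. printed_p is the p-value printed in the published
# table (NA where only "> 0.1" or nothing was printed); printed_alternative
# records the Fisher-test sidedness under which the printed value reproduces
# on recomputation (the published table mixed conventions: pooled rows are
# two-sided, sex-stratified rows one-sided).
sex	cnv_type	kind	n_non_irradiated	total_non_irradiated	n_irradiated	total_irradiated	printed_p	printed_alternative
M	L	deletion	4	75	13	75	0.018	less
M	L	duplication	1	75	0	75	NA	NA
M	S	deletion	1	75	3	75	NA	NA
M	S	duplication	0	75	0	75	NA	NA
M	all	deletion	5	75	14	75	0.024	less
M	all	duplication	1	75	0	75	NA	NA
F	L	deletion	4	81	9	67	NA	NA
F	L	duplication	0	81	1	67	NA	NA
F	S	deletion	2	81	6	67	0.085	less
F	S	duplication	2	81	0	67	NA	NA
F	all	deletion	6	81	15	67	0.009	less
F	all	duplication	2	81	1	67	NA	NA
all	L	deletion	8	156	22	142	0.004	two.sided
all	L	duplication	1	156	1	142	NA	NA
all	S	deletion	3	156	9	142	0.075	two.sided
all	S	duplication	2	156	0	142	NA	NA
all	all	deletion	11	156	29	142	0.001	two.sided
all	all	duplication	3	156	1	142	NA	NA
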