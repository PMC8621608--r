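# Confirmed de novo CNVs from a published two-generation mouse cohort
# (C57BL/6J sires exposed to 20 mGy/day gamma-rays for 400 days vs
# non-irradiated controls), as used in the package examples and the
# acceptance script. Coordinates are GRCm38, 1-based, size = end - start.
# One irradiated deletion (31 confirmed, 30 with published coordinates) is
# included with its size reconstructed from the published group geometric
# mean (n = 31, GM = 12,674 bp); it is flagged reconstructed = TRUE and has
# no coordinates. n_pos_second is the published display value (">50" for
# large events).
group	kind	mouse_id	sex	n_pos_first	n_pos_second	size_bp	chrom	start	end	reconstructed
non_irradiated	deletion	0mGyX3	M	11	>50	1103254	Chr13	66699838	67803092	FALSE
non_irradiated	deletion	0mGyH5	M	7	>50	666200	Chr2	177329278	177995478	FALSE
non_irradiated	deletion	0mGyH5	M	22	>50	146136	Chr12	40469827	40615963	FALSE
non_irradiated	deletion	0mGyG2	M	19	>50	74519	Chr1	112845241	112919760	FALSE
non_irradiated	deletion	0mGyS6	F	14	>50	56272	Chr7	102192468	102248740	FALSE
non_irradiated	deletion	0mGyK4	F	9	>50	34160	Chr3	5533449	5567609	FALSE
non_irradiated	deletion	0mGyK5	F	10	>50	25412	Chr13	54919455	54944867	FALSE
non_irradiated	deletion	0mGyJ3	F	6	>50	17346	Chr4	128415985	128433331	FALSE
non_irradiated	deletion	0mGyV2	M	1	2	461	Chr2	126675275	126675736	FALSE
non_irradiated	deletion	0mGyA3	F	1	2	212	Chr4	34844952	34845164	FALSE
non_irradiated	deletion	0mGyO7	F	1	2	153	Chr1	7323388	7323541	FALSE
non_irradiated	duplication	0mGyZ1	M	158	>50	1100262	Chr6	79988064	81088326	FALSE
non_irradiated	duplication	0mGyE4	F	1	13	1535	Chr8	123427701	123429236	FALSE
non_irradiated	duplication	0mGyG5	F	1	3	412	Chr9	49721288	49721700	FALSE
irradiated	deletion	20mGyL5	M	575	>50	1908155	Chr13	63399812	65307967	FALSE
irradiated	deletion	20mGyI5	F	200	>50	742233	Chr10	99214798	99957031	FALSE
irradiated	deletion	20mGyL8	F	145	>50	353159	Chr3	105510798	105863957	FALSE
irradiated	deletion	20mGyE1	M	83	>50	235104	Chr9	57625823	57860927	FALSE
irradiated	deletion	NA	NA	NA	NA	192082	NA	NA	NA	TRUE
irradiated	deletion	20mGyL2	M	36	>50	145401	Chr14	37914599	38060000	FALSE
irradiated	deletion	20mGyA1	M	12	>50	133572	Chr9	114085760	114219332	FALSE
irradiated	deletion	20mGyAA4	F	34	>50	102921	Chr1	117376753	117479674	FALSE
irradiated	deletion	20mGyU6	F	35	>50	76287	Chr1	172286528	172362815	FALSE
irradiated	deletion	20mGyV6	F	29	>50	75893	Chr2	45606923	45682816	FALSE
irradiated	deletion	20mGyW1	M	14	>50	40175	Chr19	54228002	54268177	FALSE
irradiated	deletion	20mGyL4	M	8	>50	32881	Chr6	138709973	138742854	FALSE
irradiated	deletion	20mGyU8	F	7	>50	29202	Chr9	100793927	100823129	FALSE
irradiated	deletion	20mGyX1	M	12	>50	28507	Chr12	92023170	92051677	FALSE
irradiated	deletion	20mGyV1	M	8	>50	22299	Chr11	111762690	111784989	FALSE
irradiated	deletion	20mGyN4	M	6	32	10224	Chr6	34932670	34942894	FALSE
irradiated	deletion	20mGyV4	F	4	>50	9424	Chr10	107833661	107843085	FALSE
irradiated	deletion	20mGyX2	F	3	40	5965	Chr14	112914840	112920805	FALSE
irradiated	deletion	20mGyAA4	F	2	33	4495	Chr17	81065337	81069832	FALSE
irradiated	deletion	20mGyU5	M	2	23	3469	Chr11	92816645	92820114	FALSE
irradiated	deletion	20mGyY1	M	2	16	3370	Chr11	105950869	105954239	FALSE
irradiated	deletion	20mGyG2	M	2	16	3286	Chr14	40993918	40997204	FALSE
irradiated	deletion	20mGyN4	M	1	19	2367	Chr4	50541636	50544003	FALSE
irradiated	deletion	20mGyG7	F	1	17	1878	Chr4	90232441	90234319	FALSE
irradiated	deletion	20mGyB5	F	1	3	1040	Chr10	69420081	69421121	FALSE
irradiated	deletion	20mGyG5	F	1	9	948	Chr1	44804456	44805404	FALSE
irradiated	deletion	20mGyX7	F	1	5	732	Chr4	21163257	21163989	FALSE
irradiated	deletion	20mGyH3	M	1	8	716	Chr3	119702208	119702924	FALSE
irradiated	deletion	20mGyY1	M	1	4	356	Chr18	27125326	27125682	FALSE
irradiated	deletion	20mGyX5	F	1	2	191	Chr12	81490882	81491073	FALSE
irradiated	deletion	20mGyB2	F	1	2	156	Chr17	4507025	4507181	FALSE
irradiated	duplication	20mGyE5	F	86	>50	305969	Chr6	48055971	48361940	FALSE
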