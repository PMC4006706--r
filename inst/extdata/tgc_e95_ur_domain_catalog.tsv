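# Catalog of the 47 underrepresented (UR) domains identified by whole-genome
# sequencing in e9.5 mouse parietal trophoblast giant cells (six individuals),
# relative to matched diploid embryos. Coordinates are mm9, 0-based half-open
# (the published 1-based start positions behave as half-open bin boundaries:
# stop - start equals the published size for every row). mean_log2/median_log2
# are the across-sample averages of the per-sample mean/median normalized log2
# coverage ratios (polyploid/diploid) over the domain; pct_depl_* are the
# published integer percent depletions, 100*(1-2^L), rounded half away from
# zero. acgh_weak marks domains detected on arrays only at a relaxed FDR.
# Gene-name annotations of the published table are omitted here.
chrom	start	end	size	mean_log2	pct_depl_mean	median_log2	pct_depl_median	acgh_weak
chr1	26170000	29150000	2980000	-0.71	39	-0.73	40	FALSE
chr1	49295000	49740000	445000	-0.53	31	-0.55	32	TRUE
chr1	101895000	105555000	3660000	-0.69	38	-0.71	39	FALSE
chr1	110610000	118845000	8235000	-0.75	41	-0.77	41	FALSE
chr1	143185000	143900000	715000	-0.60	34	-0.62	35	FALSE
chr1	147215000	150595000	3380000	-0.81	43	-0.84	44	FALSE
chr2	41835000	42470000	635000	-0.55	32	-0.55	32	FALSE
chr2	96125000	99900000	3775000	-0.78	42	-0.81	43	FALSE
chr3	43770000	47460000	3690000	-0.56	32	-0.57	33	FALSE
chr3	71440000	73815000	2375000	-0.59	34	-0.60	34	FALSE
chr3	110690000	113795000	3105000	-0.64	36	-0.65	36	FALSE
chr4	26495000	29965000	3470000	-0.67	37	-0.67	37	FALSE
chr4	37600000	38205000	605000	-0.53	31	-0.54	31	TRUE
chr4	65085000	68045000	2960000	-0.49	29	-0.49	29	FALSE
chr4	75100000	79600000	4500000	-0.79	42	-0.84	44	FALSE
chr4	90745000	92175000	1430000	-0.62	35	-0.63	35	FALSE
chr5	47605000	48815000	1210000	-0.51	30	-0.51	30	FALSE
chr5	56225000	61460000	5235000	-0.79	42	-0.81	43	FALSE
chr5	70235000	70310000	75000	-0.45	27	-0.47	28	FALSE
chr5	82380000	85120000	2740000	-0.67	37	-0.67	37	FALSE
chr6	75110000	79870000	4760000	-0.62	35	-0.62	35	FALSE
chr6	102635000	106155000	3520000	-0.65	36	-0.68	38	FALSE
chr7	60935000	61390000	455000	-0.51	30	-0.51	30	FALSE
chr8	50675000	54110000	3435000	-0.67	37	-0.66	37	FALSE
chr8	100035000	104865000	4830000	-0.78	42	-0.82	43	FALSE
chr10	47750000	48835000	1085000	-0.54	31	-0.54	31	FALSE
chr10	100945000	103700000	2755000	-0.72	39	-0.72	39	FALSE
chr11	13635000	13945000	310000	-0.48	28	-0.49	29	FALSE
chr11	37290000	39450000	2160000	-0.58	33	-0.58	33	FALSE
chr12	47225000	50645000	3420000	-0.62	35	-0.62	35	FALSE
chr12	62165000	64635000	2470000	-0.68	38	-0.70	38	FALSE
chr12	94500000	98315000	3815000	-0.84	44	-0.90	46	FALSE
chr13	86650000	88830000	2180000	-0.67	37	-0.66	37	FALSE
chr14	81615000	85375000	3760000	-0.74	40	-0.76	41	FALSE
chr14	89430000	98395000	8965000	-1.04	51	-1.12	54	FALSE
chr14	107745000	113965000	6220000	-0.95	48	-1.01	50	FALSE
chr15	14605000	23060000	8455000	-0.71	39	-0.73	40	FALSE
chr15	45850000	49435000	3585000	-0.66	37	-0.67	37	FALSE
chr16	40820000	41465000	645000	-0.48	28	-0.48	28	TRUE
chr16	67275000	69090000	1815000	-0.62	35	-0.62	35	FALSE
chr16	71335000	74650000	3315000	-0.63	35	-0.64	36	FALSE
chr16	79945000	83460000	3515000	-0.75	41	-0.79	42	FALSE
chr17	90665000	93855000	3190000	-0.71	39	-0.71	39	FALSE
chr18	16755000	18275000	1520000	-0.51	30	-0.50	29	FALSE
chr18	27570000	29040000	1470000	-0.51	30	-0.51	30	TRUE
chr18	86920000	87375000	455000	-0.51	30	-0.51	30	TRUE
chr19	50135000	51295000	1160000	-0.49	29	-0.50	29	FALSE
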