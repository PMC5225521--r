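cell_line	tf_name	motif	selection	observed_sites	reference_sites	expected_sites	ratio	mean_reads
MDA-MB-231	MYBL2	MYBB_f1	2,3,4	12	2930	6.2	1.92	2197
MDA-MB-231	BACH1	BACH1_si	1,2,3	15	3904	8.3	1.81	531
MDA-MB-231	MYC	MYC_f1	1,2,4	10	2698	5.7	1.74	3044
MDA-MB-231	MAFK	MAFK_si	2,3	16	4428	9.4	1.70	688
MDA-MB-231	RELA	TF65_f2	1,2,4	19	5467	11.6	1.63	1398
MDA-MB-231	PPARA	PPARA_f1	1,2,3	9	2747	5.8	1.54	185
MDA-MB-231	NFIA/B/C/X	NFIC_f2	1,2,3	15	4669	9.9	1.51	NA
MDA-MB-231	NFIL3	NFIL3_si	1,2,3	11	3494	7.4	1.48	474
MDA-MB-231	FOXA2	FOXA2_f1	1,2,3	36	11477	24.4	1.47	434
MDA-MB-231	REL	REL_do	1,2,3	17	5422	11.5	1.47	69
MDA-MB-231	ZFHX3	ZFHX3_f1	2,3	46	14683	31.2	1.47	66
MDA-MB-231	RXRB	RXRB_f1	1,2,4	20	6414	13.6	1.47	1015
MDA-MB-231	SMARCC1	SMRC1_f1	1,4	20	6443	13.7	1.46	1478
MDA-MB-231	ETV5	ETV5_f1	2,3	16	5199	11.1	1.45	641
MDA-MB-231	NR3C1	GCR_si	1,2,4	15	4910	10.4	1.44	1087
T-47D	MBD2	MBD2_si	1,2,3,4	101	6664	39.6	2.55	571
T-47D	TFAP2A	AP2A_f2	1,2,3	115	10363	61.6	1.87	941
T-47D	E4F1	E4F1_f1	2,3	18	1750	10.4	1.73	310
T-47D	SP1	SP1_f1	1,2	392	41453	246.3	1.59	838
T-47D	CUX1	CUX1_f1	1,2,3	13	1462	8.7	1.50	141
T-47D	E2F2	E2F2_f1	1,2	17	1941	11.5	1.47	215
T-47D	AHR	AHR_si	1,2,3	9	1030	6.1	1.47	791
T-47D	SP2	SP2_si	1,2	140	16512	98.1	1.43	672
T-47D	CREB1	CREB1_f1	1,2,3	23	2720	16.2	1.42	177
T-47D	CBFB	PEBB_f1	1,2,3,4	46	5461	32.4	1.42	457
T-47D	ZIC2	ZIC2_f1	1,2,3	46	5487	32.6	1.41	118
T-47D	ZFX	ZFX_f1	1,2,3	127	15650	93.0	1.37	287
T-47D	HIF1A	HIF1A_si	1,2,3,4	15	1890	11.2	1.34	1847
T-47D	E2F3	E2F3_si	1,2,3	16	2019	12.0	1.33	322
T-47D	XBP1	XBP1_f1	1,3,4	12	1545	9.2	1.31	22744
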