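phenotype	gene	cytoband	snps_in_predictor	study	zscore	pvalue	fdr
overall	TP53INP2	20q11.22	6	AABC	-2.536	1.12e-02	NA
overall	TP53INP2	20q11.22	6	CGEMS	-0.953	3.41e-01	NA
overall	TP53INP2	20q11.22	6	ROOT	-3.023	2.50e-03	NA
overall	TP53INP2	20q11.22	6	SBCGS	-1.683	9.23e-02	NA
overall	TP53INP2	20q11.22	6	Total	-4.180	2.91e-05	0.34
overall	BAG3	10q26.11	18	AABC	-2.109	3.49e-02	NA
overall	BAG3	10q26.11	18	CGEMS	-1.145	2.52e-01	NA
overall	BAG3	10q26.11	18	ROOT	-3.003	2.67e-03	NA
overall	BAG3	10q26.11	18	SBCGS	-1.074	2.83e-01	NA
overall	BAG3	10q26.11	18	Total	-3.660	2.52e-04	0.77
overall	POLN	4p16.3	39	AABC	-2.291	2.20e-02	NA
overall	POLN	4p16.3	39	CGEMS	-2.614	8.96e-03	NA
overall	POLN	4p16.3	39	ROOT	-0.942	3.46e-01	NA
overall	POLN	4p16.3	39	SBCGS	-1.624	1.04e-01	NA
overall	POLN	4p16.3	39	Total	-3.644	2.68e-04	0.77
overall	WDR37	10p15.3	9	AABC	-1.637	1.02e-01	NA
overall	WDR37	10p15.3	9	CGEMS	-0.747	4.55e-01	NA
overall	WDR37	10p15.3	9	ROOT	-0.292	7.70e-01	NA
overall	WDR37	10p15.3	9	SBCGS	-4.144	3.42e-05	NA
overall	WDR37	10p15.3	9	Total	-3.629	2.84e-04	0.77
overall	TTLL5	14q24.3	26	AABC	2.717	6.59e-03	NA
overall	TTLL5	14q24.3	26	CGEMS	2.087	3.69e-02	NA
overall	TTLL5	14q24.3	26	ROOT	1.189	2.35e-01	NA
overall	TTLL5	14q24.3	26	SBCGS	1.206	2.28e-01	NA
overall	TTLL5	14q24.3	26	Total	3.588	3.33e-04	0.77
overall	HP	16q22.2	19	AABC	2.424	1.53e-02	NA
overall	HP	16q22.2	19	CGEMS	1.961	4.99e-02	NA
overall	HP	16q22.2	19	ROOT	1.598	1.10e-01	NA
overall	HP	16q22.2	19	SBCGS	1.147	2.52e-01	NA
overall	HP	16q22.2	19	Total	3.529	4.18e-04	0.77
overall	VTI1B	14q24.1	1	AABC	1.433	1.52e-01	NA
overall	VTI1B	14q24.1	1	CGEMS	2.790	5.28e-03	NA
overall	VTI1B	14q24.1	1	ROOT	0.902	3.67e-01	NA
overall	VTI1B	14q24.1	1	SBCGS	2.151	3.15e-02	NA
overall	VTI1B	14q24.1	1	Total	3.471	5.18e-04	0.77
overall	HLA-DMA	6p21.32	30	AABC	-2.001	4.54e-02	NA
overall	HLA-DMA	6p21.32	30	CGEMS	-0.756	4.50e-01	NA
overall	HLA-DMA	6p21.32	30	ROOT	-1.603	1.09e-01	NA
overall	HLA-DMA	6p21.32	30	SBCGS	-2.293	2.19e-02	NA
overall	HLA-DMA	6p21.32	30	Total	-3.456	5.47e-04	0.77
overall	MYOM2	8p23.3	109	AABC	2.338	1.94e-02	NA
overall	MYOM2	8p23.3	109	CGEMS	-0.051	9.59e-01	NA
overall	MYOM2	8p23.3	109	ROOT	2.153	3.14e-02	NA
overall	MYOM2	8p23.3	109	SBCGS	1.955	5.06e-02	NA
overall	MYOM2	8p23.3	109	Total	3.430	6.04e-04	0.77
overall	MYO9B	19p13.11	6	AABC	1.643	1.00e-01	NA
overall	MYO9B	19p13.11	6	CGEMS	0.887	3.75e-01	NA
overall	MYO9B	19p13.11	6	ROOT	1.473	1.41e-01	NA
overall	MYO9B	19p13.11	6	SBCGS	2.549	1.08e-02	NA
overall	MYO9B	19p13.11	6	Total	3.373	7.44e-04	0.81
overall	ZNF202	11q24.1	15	AABC	2.214	2.69e-02	NA
overall	ZNF202	11q24.1	15	CGEMS	1.675	9.39e-02	NA
overall	ZNF202	11q24.1	15	ROOT	0.003	9.98e-01	NA
overall	ZNF202	11q24.1	15	SBCGS	2.644	8.20e-03	NA
overall	ZNF202	11q24.1	15	Total	3.363	7.71e-04	0.81
er_negative	TP53INP2	20q11.22	6	AABC	-3.708	2.09e-04	NA
er_negative	TP53INP2	20q11.22	6	BPC3	-2.919	3.51e-03	NA
er_negative	TP53INP2	20q11.22	6	ROOT	-2.703	6.87e-03	NA
er_negative	TP53INP2	20q11.22	6	SBCGS	-0.417	6.77e-01	NA
er_negative	TP53INP2	20q11.22	6	Total	-5.013	5.35e-07	0.0062
er_negative	HP	16q22.2	20	AABC	1.424	1.54e-01	NA
er_negative	HP	16q22.2	20	BPC3	3.302	9.61e-04	NA
er_negative	HP	16q22.2	20	ROOT	1.851	6.41e-02	NA
er_negative	HP	16q22.2	20	SBCGS	1.749	8.03e-02	NA
er_negative	HP	16q22.2	20	Total	4.300	1.70e-05	0.098
er_negative	DHODH	16q22.2	58	AABC	-1.121	2.62e-01	NA
er_negative	DHODH	16q22.2	58	BPC3	-4.700	2.61e-06	NA
er_negative	DHODH	16q22.2	58	ROOT	1.020	3.08e-01	NA
er_negative	DHODH	16q22.2	58	SBCGS	-1.859	6.31e-02	NA
er_negative	DHODH	16q22.2	58	Total	-4.119	3.80e-05	0.15
er_negative	YJEFN3	19p13.11	20	AABC	-2.650	8.05e-03	NA
er_negative	YJEFN3	19p13.11	20	BPC3	-2.797	5.16e-03	NA
er_negative	YJEFN3	19p13.11	20	ROOT	0.154	8.78e-01	NA
er_negative	YJEFN3	19p13.11	20	SBCGS	-1.549	1.21e-01	NA
er_negative	YJEFN3	19p13.11	20	Total	-3.810	1.39e-04	0.34
er_negative	MAP1LC3A	20q11.22	49	AABC	-2.077	3.78e-02	NA
er_negative	MAP1LC3A	20q11.22	49	BPC3	-2.922	3.48e-03	NA
er_negative	MAP1LC3A	20q11.22	49	ROOT	-1.751	7.99e-02	NA
er_negative	MAP1LC3A	20q11.22	49	SBCGS	-0.157	8.75e-01	NA
er_negative	MAP1LC3A	20q11.22	49	Total	-3.734	1.88e-04	0.34
er_negative	DPY19L1	7p14.2	24	AABC	2.188	2.87e-02	NA
er_negative	DPY19L1	7p14.2	24	BPC3	3.035	2.41e-03	NA
er_negative	DPY19L1	7p14.2	24	ROOT	0.672	5.01e-01	NA
er_negative	DPY19L1	7p14.2	24	SBCGS	0.791	4.29e-01	NA
er_negative	DPY19L1	7p14.2	24	Total	3.731	1.91e-04	0.34
er_negative	GCOM1	15q21.3	75	AABC	-1.841	6.56e-02	NA
er_negative	GCOM1	15q21.3	75	BPC3	-3.295	9.85e-04	NA
er_negative	GCOM1	15q21.3	75	ROOT	-0.854	3.93e-01	NA
er_negative	GCOM1	15q21.3	75	SBCGS	-0.525	5.99e-01	NA
er_negative	GCOM1	15q21.3	75	Total	-3.689	2.25e-04	0.34
er_negative	AMOTL1	11q21	14	AABC	2.155	3.12e-02	NA
er_negative	AMOTL1	11q21	14	BPC3	2.118	3.42e-02	NA
er_negative	AMOTL1	11q21	14	ROOT	0.448	6.54e-01	NA
er_negative	AMOTL1	11q21	14	SBCGS	2.509	1.21e-02	NA
er_negative	AMOTL1	11q21	14	Total	3.675	2.38e-04	0.34
er_negative	ITCH	20q11.22	12	AABC	-1.597	1.10e-01	NA
er_negative	ITCH	20q11.22	12	BPC3	-3.861	1.13e-04	NA
er_negative	ITCH	20q11.22	12	ROOT	0.203	8.39e-01	NA
er_negative	ITCH	20q11.22	12	SBCGS	-0.318	7.51e-01	NA
er_negative	ITCH	20q11.22	12	Total	-3.494	4.77e-04	0.61
er_negative	TRPC4AP	20q11.22	26	AABC	2.385	1.71e-02	NA
er_negative	TRPC4AP	20q11.22	26	BPC3	1.899	5.76e-02	NA
er_negative	TRPC4AP	20q11.22	26	ROOT	2.536	1.12e-02	NA
er_negative	TRPC4AP	20q11.22	26	SBCGS	0.127	8.99e-01	NA
er_negative	TRPC4AP	20q11.22	26	Total	3.466	5.28e-04	0.61
er_negative	SNX24	5q23.2	3	AABC	-0.902	3.67e-01	NA
er_negative	SNX24	5q23.2	3	BPC3	-2.235	2.54e-02	NA
er_negative	SNX24	5q23.2	3	ROOT	-1.612	1.07e-01	NA
er_negative	SNX24	5q23.2	3	SBCGS	-2.022	4.32e-02	NA
er_negative	SNX24	5q23.2	3	Total	-3.327	8.77e-04	0.91
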