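# Orofacial cleft (NSCL/P) candidate lead-SNPs from published GWAS; best reported association p-value per SNP.
snp_id	region	position_bp	reported_p	candidate_gene
rs560426	1p22	94553438	5.01E-12
rs481931	1p22	94570016	1.06E-12
rs4147803	1p22	94582293	7.97E-12
rs66515264	1p22	94558110	4.14E-17
rs742071	1p36	18979874	7.02E-09	PAX7
rs4920524	1p36	18978372	3.72E-09
rs9439713	1p36	18972776	6.02E-13
rs861020	1q32	209977111	3.24E-12
rs2235371	1q32	209964080	8.69E-22
rs1044516	1q32	209959614	6.57E-13
rs596731	1q32	209993801	3.77E-10
rs742214	1q32	209960925	1.62E-19
rs2064163	1q32	210048819	8.6E-19
rs642961	1q32	209989270	2.76E-15
rs9430019	1q32	210050794	1.68E-12
rs7590268	2p21	43540125	1.25E-08	THADA
rs6740960	2p21	42181679	5.71E-13	PKDCC
rs7552	2p24.2	16733928	4.22E-08
rs7566780	2p24.2	16729357	4.28E-09
rs10172734	2p24.2	16733054	2.89E-20
rs287980	2p25.1	9971366	1.94E-08
rs7632427	3p11.1	89534377	3.9E-08
rs76479869	3q28	189553372	1.16E-08
rs338217	3q29	2979676	9.70E-10
rs34246903	4p16.2	4794195	4.45E-08	MSX1
rs1907989	4p16.2	4818925	1.58E-08
rs908822	4q28.1	124906257	4.33E-08
rs10462065	5p12	44068846	1.12E-08
rs9381107	6p24.3	9469238	2.72E-09
rs13317	8p11.23	38269514	3.96E-08
rs12543318	8q21	88868340	1.9E-08
rs1034832	8q21	88918331	1.35E-10
rs957448	8q22.1	95541302	9.6E-13
rs12681366	8q22.1	95401265	2.35E-10
rs987525	8q24	129946154	1.11E-16
rs7845615	8q24	129888794	1.03E-10
rs7017252	8q24	129950844	8.47E-16
rs55658222	8q24	129976136	8.3E-44
rs7871395	9q22.2	92209587	6.06E-09
rs10512248	9q22.32	98259703	5.1E-10	PTCH1
rs7078160	10q25	118827560	1.07E-07
rs6585429	10q25	118893231	7.14E-13
rs3741442	12q13.13	53346750	3.72E-12
rs705704	12q13.2	56435412	1.29E-09
rs2304269	12q21.1	72080272	1.32E-12
rs7967428	12q21.1	72089040	3.08E-12
rs9545308	13q31.1	80639405	2E-09
rs8001641	13q31.1	80692811	2.62E-10
rs11841646	13q31.1	80679302	3.62E-10
rs7148069	14q22.1	51839645	1.69E-08
rs4901118	14q22.1	51856109	6.94E-10
rs1243573	14q32.13	95379583	8.61E-10
rs1258763	15q13	33050423	8.13E-14
rs1873147	15q22.2	63312632	2.81E-08
rs28689146	15q24	75005575	6.61E-09
rs11072494	15q24	74889163	2.4E-08
rs8049367	16p13.3	3980445	8.98E-12
rs2283487	16p13.3	3969886	1.27E-10
rs17136624	16p13.3	3996282	3.82E-10
rs9788972	17p13.1	8919630	7.05E-09
rs4791774	17p13.1	8930220	5.05E-19
rs11273201	17p13.1	8930225	7.84E-12
rs7406226	17p13.1	8914693	1.46E-08
rs2872615	17p13.1	8929845	8.81E-12
rs1880646	17p13.1	8929845	1.69E-11
rs12944377	17p13.1	8947708	8.23E-21
rs4968247	17q21.32	44988703	8.7E-10
rs1838105	17q21.32	45008935	1.31E-11
rs227731	17q22	54773238	1.07E-08	NOG
rs1588366	17q23.2	61076428	1.41E-08
rs3746101	19p13.3	2050823	2.44E-08
rs73039428	19q12	33521150	2.92E-08
rs13041247	20q12	39269074	1.44E-11
rs6129653	20q12	39275603	8.57E-12
rs6072081	20q12	39261054	1.87E-12
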