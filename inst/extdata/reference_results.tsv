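metabolite	n_below_lb	gm_case	gm_case_lo	gm_case_hi	gm_control	gm_control_lo	gm_control_hi	fc	p_value	p_censored	fdr_p
C10	9	1,983	1,371	2,869	0,579	0,402	0,832	3,43	0,0001	yes	0,0001
lysoPC a C20:3	0	1,722	1,243	2,386	0,608	0,444	0,831	2,83	0,0001	yes	0,0001
C14:1	20	1,808	1,141	2,866	0,405	0,249	0,658	4,47	0,0001	yes	0,0002
lysoPC a C17:0	9	1,945	1,326	2,854	0,604	0,415	0,879	3,22	0,0001	yes	0,0002
C5	17	1,563	1,010	2,419	0,407	0,260	0,639	3,84	0,0001	yes	0,0003
lysoPC a C18:2	0	1,512	1,073	2,132	0,607	0,437	0,845	2,49	0,0001	no	0,0016
lysoPC a C16:1	0	1,532	1,080	2,173	0,613	0,438	0,857	2,50	0,0001	no	0,0017
lysoPC_s	0	1,544	1,082	2,203	0,670	0,476	0,942	2,31	0,0004	no	0,0079
PC ae C36:4	0	1,582	1,143	2,190	0,756	0,553	1,032	2,09	0,0006	no	0,0108
lysoPC a C16:0	0	1,564	1,092	2,239	0,703	0,498	0,993	2,22	0,0008	no	0,0127
PC ae C38:5	0	1,615	1,151	2,267	0,766	0,553	1,061	2,11	0,0009	no	0,0133
PC ae C32:1	0	1,499	1,081	2,079	0,739	0,540	1,011	2,03	0,0011	no	0,0145
lysoPC a C18:1	0	1,385	0,969	1,980	0,642	0,456	0,905	2,16	0,0011	no	0,0145
PC aa C34:1	0	1,550	1,125	2,135	0,786	0,578	1,070	1,97	0,0014	no	0,0163
PC aa C36:3	0	1,530	1,105	2,119	0,776	0,568	1,061	1,97	0,0016	no	0,0177
PC ae C36:3	0	1,566	1,121	2,189	0,794	0,576	1,095	1,97	0,0021	no	0,0216
PC aa C36:2	0	1,647	1,163	2,332	0,815	0,584	1,139	2,02	0,0022	no	0,0216
lysoPC a C26:0	27	1,163	0,631	2,144	0,320	0,164	0,623	3,64	0,0023	no	0,0216
PC aa_s	0	1,523	1,099	2,112	0,797	0,582	1,090	1,91	0,0027	no	0,0236
SM (OH) C22:2	23	1,401	0,799	2,458	0,463	0,259	0,830	3,02	0,0044	no	0,0329
PC ae C36:5	0	1,501	1,067	2,111	0,789	0,569	1,095	1,90	0,0044	no	0,0329
PC ae C42:0	2	1,287	0,906	1,830	0,666	0,474	0,934	1,93	0,0046	no	0,0329
PC ae C34:1	0	1,488	1,075	2,062	0,811	0,593	1,110	1,83	0,0049	no	0,0329
C3-DC (C4-OH)	30	1,112	0,576	2,148	0,292	0,137	0,622	3,81	0,0049	no	0,0329
PC ae C36:0	0	1,442	1,013	2,054	0,748	0,533	1,050	1,93	0,0049	no	0,0329
PC aa C32:0	0	1,484	1,082	2,037	0,834	0,615	1,130	1,78	0,0058	no	0,0372
PC ae C34:2	0	1,503	1,074	2,103	0,821	0,595	1,134	1,83	0,0065	no	0,0400
PC aa C38:5	0	1,528	1,077	2,167	0,821	0,587	1,148	1,86	0,0072	no	0,0426
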