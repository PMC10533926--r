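snp	effect_allele	other_allele	beta	se	pval
rs10936600	T	A	-0.086	0.006	1.35E-46
rs13137667	C	T	0.077	0.014	3.80E-08
rs228595	A	G	-0.029	0.005	6.63E-09
rs2302588	C	G	0.048	0.008	1.97E-09
rs2736176	C	G	0.035	0.006	5.43E-09
rs3219104	C	A	0.042	0.006	2.56E-12
rs3785074	G	A	0.035	0.006	5.43E-09
rs4691895	C	G	0.058	0.006	4.18E-22
rs59294613	A	C	-0.041	0.006	8.30E-12
rs62053580	G	A	-0.039	0.007	2.53E-08
rs7194734	T	C	-0.037	0.006	6.97E-10
rs75691080	T	C	-0.067	0.009	9.74E-14
rs7705526	A	C	0.082	0.006	1.61E-42
rs8105767	G	A	0.039	0.005	6.19E-15
rs9419958	C	T	-0.064	0.007	6.08E-20
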