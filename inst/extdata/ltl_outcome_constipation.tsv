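snp	effect_allele	other_allele	beta	se	pval
rs10936600	T	A	-0.014	0.010	0.183
rs13137667	C	T	0.012	0.030	0.691
rs228595	A	G	0.003	0.009	0.772
rs2302588	C	G	-0.027	0.019	0.156
rs2736176	C	G	0.013	0.010	0.214
rs3219104	C	A	0.017	0.011	0.111
rs3785074	G	A	-0.001	0.011	0.902
rs4691895	C	G	0.002	0.012	0.876
rs59294613	A	C	0.014	0.011	0.194
rs62053580	G	A	-0.001	0.015	0.970
rs7194734	T	C	-0.025	0.012	0.043
rs75691080	T	C	-0.004	0.015	0.789
rs7705526	A	C	-0.002	0.010	0.867
rs8105767	G	A	0.003	0.010	0.793
rs9419958	C	T	0.034	0.014	0.020
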