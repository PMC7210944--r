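taxon	marker	mz	sequence	n_hyd	note
Bos sp.	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Bos sp.	A	1208.642			synthetic marker series for testing
Bos sp.	B	1427.715			synthetic marker series for testing
Bos sp.	C	1580.803			synthetic marker series for testing
Bos sp.	D	2131.096			synthetic marker series for testing
Bos sp.	E	2792.428			synthetic marker series for testing
Bos sp.	F	2853.472			synthetic marker series for testing
Bos sp.	G	3093.482			synthetic marker series for testing
Bison sp.	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Bison sp.	A	1208.642			synthetic marker series for testing
Bison sp.	B	1427.715			synthetic marker series for testing
Bison sp.	C	1580.803			synthetic marker series for testing
Bison sp.	D	2131.096			synthetic marker series for testing
Bison sp.	E	2792.428			synthetic marker series for testing
Bison sp.	F	2853.472			synthetic marker series for testing
Bison sp.	G	3093.482			synthetic marker series for testing
Ovibos moschatus	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Ovibos moschatus	A	1208.642			synthetic marker series for testing
Ovibos moschatus	B	1427.715			synthetic marker series for testing
Ovibos moschatus	C	1580.803			synthetic marker series for testing
Ovibos moschatus	D	2131.096			synthetic marker series for testing
Ovibos moschatus	E	2792.428			synthetic marker series for testing
Ovibos moschatus	F	2869.467			synthetic marker series for testing
Ovibos moschatus	G	3077.451			synthetic marker series for testing
Rangifer tarandus	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Rangifer tarandus	A	1180.615			synthetic marker series for testing
Rangifer tarandus	B	1427.715			synthetic marker series for testing
Rangifer tarandus	C	1550.772			synthetic marker series for testing
Rangifer tarandus	D	2131.096			synthetic marker series for testing
Rangifer tarandus	E	2808.423			synthetic marker series for testing
Rangifer tarandus	F	2883.493			synthetic marker series for testing
Rangifer tarandus	G	3033.435			synthetic marker series for testing
Cervus elaphus	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Cervus elaphus	A	1180.615			synthetic marker series for testing
Cervus elaphus	B	1427.715			synthetic marker series for testing
Cervus elaphus	C	1566.767			synthetic marker series for testing
Cervus elaphus	D	2131.096			synthetic marker series for testing
Cervus elaphus	E	2808.423			synthetic marker series for testing
Cervus elaphus	F	2899.488			synthetic marker series for testing
Cervus elaphus	G	3059.450			synthetic marker series for testing
Equus sp.	P1	1105.575	GVQGPPGPAGPR	1	COL1 P1 peptide, one hydroxyproline
Equus sp.	A	1208.642			synthetic marker series for testing
Equus sp.	B	1453.730			synthetic marker series for testing
Equus sp.	C	1550.772			synthetic marker series for testing
Equus sp.	D	2145.112			synthetic marker series for testing
Equus sp.	E	2824.418			synthetic marker series for testing
Equus sp.	F	2899.488			synthetic marker series for testing
Equus sp.	G	3093.482			synthetic marker series for testing
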