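layer	taxon	common_name	nisp	ribs	group
L-3A	Capreolus capreolus	roe deer	4	0	
L-3A	Cervus elaphus	red deer	7	0	
L-3A	Rangifer tarandus	reindeer	12	0	
L-3A	Cervus/Rangifer	red deer/reindeer	22	2	medium ungulate
L-3A	Cervid	cervid (antler tips)	1	0	
L-3A	Cervid/Saiga	cervid/saiga	1	0	
L-3A	Bison sp./Bos sp.	bison/aurochs	10	2	large bovid
L-3A	large ungulate	large ungulate	10	1	large bovid
L-3A	large carnivore	large carnivore	1	0	
L-3B	Lepus sp.	hare	3	0	
L-3B	Capreolus capreolus	roe deer	1	0	
L-3B	Rangifer tarandus	reindeer	264	1	medium ungulate
L-3B	Cervus/Rangifer	red deer/reindeer	219	37	medium ungulate
L-3B	Cervid	cervid (antler tips)	1	0	
L-3B	Bison sp./Bos sp.	bison/aurochs	16	3	large bovid
L-3B	large ungulate	large ungulate	35	1	large bovid
L-3B	Rhinocerotid	rhinoceros	1	0	
L-3B	medium carnivore	medium carnivore	1	0	
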