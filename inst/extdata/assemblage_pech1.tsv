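layer	taxon	common_name	nisp	ribs	group
Pech I-4	Vulpes vulpes	fox	1	0	
Pech I-4	Lepus sp.	hare	2	0	
Pech I-4	Capreolus capreolus	roe deer	44	3	roe deer
Pech I-4	Cervus elaphus	red deer	327	13	red deer
Pech I-4	Rangifer tarandus	reindeer	12	0	
Pech I-4	Cervus/Rangifer	red deer/reindeer	12	0	
Pech I-4	Bison sp./Bos sp.	bison/aurochs	114	10	large bovid
Pech I-4	Equus caballus	horse	6	0	
Pech I-4	small ungulate	small ungulate (size class 1)	1	0	
Pech I-4	ungulate 1/2	ungulate size class 1/2	2	1	small ungulate
Pech I-4	medium ungulate	medium ungulate (size class 2)	59	32	medium ungulate
Pech I-4	ungulate 2/3	ungulate size class 2/3	16	15	medium ungulate
Pech I-4	ungulate 2/4	ungulate size class 2/4	15	0	
Pech I-4	large ungulate	large ungulate (size class 3/4)	29	23	large ungulate
Pech I-4	avifauna	avifauna	2	0	
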