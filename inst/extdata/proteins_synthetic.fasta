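>CO1A1_SYNBOV synthetic collagen alpha-1(I) fragment OS=Bos taurus
GPAGPPGKDGEAGAQGPPGPAGPAGERGVQGPPGPAGPRGDKGETGEQGDRGIKGHRGFS
GLQGPPGPPGSPGEQGPSGASGPAGPRGPPGSAGAPGKDGLNGLPGPIGPPGPRGRTGDA
GPVGPPGPPGPPGPPGPPSAGFDFSFLPQPPQEK
>CO1A2_SYNBOV synthetic collagen alpha-2(I) fragment OS=Bos taurus
GPPGESGAAGPTGPIGSRGPSGPPGPDGNKGEPGVVGAVGTAGPSGPSGLPGERGAAGIP
GGKGEKGETGLRGDIGSPGRDGARGAPGAVGAPGPAGATGDRGEAGAAGPAGPAGPR
>TRYP_SYNPIG synthetic cationic trypsin fragment OS=Sus scrofa
IVGGYTCAANSIPYQVSLNSGSHFCGGSLINSQWVVSAAHCYKSRIQVRLGEHNIDVLEG
NEQFINAAKIITHPNFNGNTLDNDIMLIKLSSPATLNSRVATVSLPR
>K2C1_SYNHUM synthetic keratin type II cytoskeletal 1 fragment OS=Homo sapiens
SGGGFSSGSAGIINYQRRTTSSSTRRSGGGGGRFSSCGGGGGSFGAGGGFGSRSLVNLGG
SKSISISVARGGGRGSGFGGGYGGGGFGGGGFGGGGIGGVLTAAR
>K1C10_SYNHUM synthetic keratin type I cytoskeletal 10 fragment OS=Homo sapiens
SVRYSSSKHYSSSRSGGGGGGGGCGGGGGVSSLRISSSKGSLGGGFSSGGFSGGSFSRGS
SGGGCFGGSSGGYGGLGGFGGGSFRGSYGSSSFGGSYGGSFGGGNFGGGSFGGGSFGGGG
>ALBU_SYNBOV synthetic serum albumin fragment OS=Bos taurus
DTHKSEIAHRFKDLGEEHFKGLVLIAFSQYLQQCPFDEHVKLVNELTEFAKTCVADESHA
GCEKSLHTLFGDELCKVASLRETYGDMADCCEKQEPERNECFLSHKDDSPDLPK
>HBA_SYNBOV synthetic hemoglobin subunit alpha fragment OS=Bos taurus
VLSAADKGNVKAAWGKVGGHAAEYGAEALERMFLSFPTTKTYFPHFDLSHGSAQVKGHGA
KVAAALTKAVEHLDDLPGALSELSDLHAHKLR
>HBB_SYNBOV synthetic hemoglobin subunit beta fragment OS=Bos taurus
MLTAEEKAAVTAFWGKVKVDEVGGEALGRLLVVYPWTQRFFESFGDLSTADAVMNNPKVK
AHGKKVLDSFSNGMKHLDDLKGTFAALSELHCDKLHVDPENFK
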