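# Per-phylum counts of cultured rumen bacteria and 16S survey OTUs.
# cultured_genera: rumen bacterial genera known in culture (collections,
#   literature, NCBI/RDP); cultured_isolates: cultures of rumen origin held
#   by five international culture collections; kim_otus: OTU counts from an
#   earlier rumen census for comparison; this_study_otus: rumen universal
#   OTUs from the seven-survey meta-analysis.  Dashes in the source table
#   are recorded as 0.
phylum	cultured_genera	cultured_isolates	kim_otus	this_study_otus
Actinobacteria	11	25	107	41
Bacteroidetes	6	5	3605	907
Cyanobacteria	0	0	1	3
Fibrobacteres	1	7	112	16
Firmicutes	45	90	7797	1263
Fusobacteria	1	0	10	1
Planctomycetes	0	0	17	1
Proteobacteria	20	16	928	64
Spirochaetes	1	2	144	48
Synergistetes	1	1	382	11
Acidobacteria	0	0	1	3
Tenericutes	2	0	16	21
Chloroflexi	0	0	14	4
Deferribacteres	0	0	4	0
Lentisphaerae	0	0	12	2
Verrucomicrobia	0	0	57	1
OP10	0	0	1	0
SR1	0	0	32	4
TM7	0	0	39	14
Nitrospira	0	0	0	1
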