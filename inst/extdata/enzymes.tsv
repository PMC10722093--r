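name	site	cut_offset
# curated common 4- and 6-cutters; site in IUPAC, cut_offset = top-strand
# cut position in bp from site start
EcoRI	GAATTC	1
BamHI	GGATCC	1
HindIII	AAGCTT	1
EcoRV	GATATC	3
DraI	TTTAAA	3
XbaI	TCTAGA	1
PstI	CTGCAG	5
SacI	GAGCTC	5
SalI	GTCGAC	1
SpeI	ACTAGT	1
SphI	GCATGC	5
KpnI	GGTACC	5
NcoI	CCATGG	1
NdeI	CATATG	2
BglII	AGATCT	1
XhoI	CTCGAG	1
ApoI	RAATTY	1
BstNI	CCWGG	2
ScrFI	CCNGG	2
DdeI	CTNAG	1
HinfI	GANTC	1
AluI	AGCT	2
HaeIII	GGCC	2
HhaI	GCGC	3
HpaII	CCGG	1
MboI	GATC	0
MseI	TTAA	1
RsaI	GTAC	2
TaqI	TCGA	1
NlaIII	CATG	4
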