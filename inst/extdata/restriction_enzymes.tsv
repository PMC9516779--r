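name	motif
AluI	AGCT
AatII	GACGTC
ApoI	RAATTY
AvaII	GGWCC
BamHI	GGATCC
BglII	AGATCT
BsaAI	YACGTR
BsmAI	GTCTC
BstNI	CCWGG
ClaI	ATCGAT
DdeI	CTNAG
DpnII	GATC
DraI	TTTAAA
DrdI	GACNNNNNNGTC
EcoRI	GAATTC
EcoRV	GATATC
Fnu4HI	GCNGC
HaeIII	GGCC
HhaI	GCGC
HincII	GTYRAC
HindIII	AAGCTT
HinfI	GANTC
HpaII	CCGG
KpnI	GGTACC
MluI	ACGCGT
MseI	TTAA
MslI	CAYNNNNRTG
NcoI	CCATGG
NdeI	CATATG
NlaIII	CATG
NotI	GCGGCCGC
NsiI	ATGCAT
PstI	CTGCAG
PvuII	CAGCTG
RsaI	GTAC
SacI	GAGCTC
SalI	GTCGAC
Sau96I	GGNCC
ScaI	AGTACT
SpeI	ACTAGT
SphI	GCATGC
StuI	AGGCCT
TaqI	TCGA
Tsp509I	AATT
XbaI	TCTAGA
XhoI	CTCGAG
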