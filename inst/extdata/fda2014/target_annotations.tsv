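# per-gene rows reconstructed to match the published category totals
gene_symbol	location	family	subfamily
ABL1	nucleus	Enzyme	Tyrosine kinase
ACPP	extracellular space	Enzyme	Phosphatase
ALK	plasma membrane	Enzyme	Tyrosine kinase
AR	nucleus	Receptor	Ligand-dependent nuclear receptor
BCR-ABL	cytoplasm	Enzyme	Tyrosine kinase
BRAF	cytoplasm	Enzyme	Serine/threonine kinase
BTK	cytoplasm	Enzyme	Tyrosine kinase
CD19	plasma membrane	Antigen	Antigen
CD33	plasma membrane	Antigen	Antigen
CD3D	plasma membrane	Antigen	Antigen
CD52	plasma membrane	Antigen	Antigen
CRBN	cytoplasm	Enzyme	E3 ligase
CSF1R	plasma membrane	Enzyme	Tyrosine kinase
CTLA4	plasma membrane	Receptor	Transmembrane receptor
CYP17A1	cytoplasm	Enzyme	Monooxygenases
CYP19A1	cytoplasm	Enzyme	Monooxygenases
DDR2	plasma membrane	Enzyme	Tyrosine kinase
DNMT1	nucleus	Enzyme	Epigenetic enzyme
EGFR	plasma membrane	Enzyme	Tyrosine kinase
EPHA2	plasma membrane	Enzyme	Tyrosine kinase
ERBB2	plasma membrane	Enzyme	Tyrosine kinase
ERBB4	plasma membrane	Enzyme	Tyrosine kinase
ESR1	nucleus	Receptor	Ligand-dependent nuclear receptor
ESR2	nucleus	Receptor	Ligand-dependent nuclear receptor
FCGR1A	plasma membrane	Receptor	Transmembrane receptor
FGF1	extracellular space	Growth factor	Growth factor
FGFR1	plasma membrane	Enzyme	Tyrosine kinase
FGFR2	plasma membrane	Enzyme	Tyrosine kinase
FGFR3	plasma membrane	Enzyme	Tyrosine kinase
FLT1	plasma membrane	Enzyme	Tyrosine kinase
FLT3	plasma membrane	Enzyme	Tyrosine kinase
FLT4	plasma membrane	Enzyme	Tyrosine kinase
FRK	cytoplasm	Enzyme	Serine/threonine kinase
GNRH1	extracellular space	Hormone	Hormone
GNRHR	plasma membrane	Receptor	G-protein coupled receptor
HDAC1	nucleus	Enzyme	Epigenetic enzyme
HDAC2	nucleus	Enzyme	Epigenetic enzyme
HDAC3	nucleus	Enzyme	Epigenetic enzyme
HDAC6	cytoplasm	Enzyme	Epigenetic enzyme
IFNAR1	plasma membrane	Receptor	Transmembrane receptor
IFNAR2	plasma membrane	Receptor	Transmembrane receptor
IL2RA	plasma membrane	Receptor	Transmembrane receptor
IL2RB	plasma membrane	Receptor	Transmembrane receptor
IL2RG	plasma membrane	Receptor	Transmembrane receptor
ITK	cytoplasm	Enzyme	Tyrosine kinase
JAK1	cytoplasm	Enzyme	Tyrosine kinase
JAK2	cytoplasm	Enzyme	Tyrosine kinase
KDR	plasma membrane	Enzyme	Tyrosine kinase
KIT	plasma membrane	Enzyme	Tyrosine kinase
LDLR	plasma membrane	Transporter	Transporter
LHCGR	plasma membrane	Receptor	G-protein coupled receptor
LIMK1	cytoplasm	Enzyme	Serine/threonine kinase
MAP1A	cytoplasm	Other	Other
MAP2	cytoplasm	Other	Other
MAP2K1	cytoplasm	Enzyme	Threonine/tyrosine-protein kinase
MAP2K2	cytoplasm	Enzyme	Threonine/tyrosine-protein kinase
MAPK11	nucleus	Enzyme	Serine/threonine kinase
MET	plasma membrane	Enzyme	Tyrosine kinase
MS4A1	plasma membrane	Antigen	Antigen
MTOR	cytoplasm	Enzyme	Serine/threonine kinase
NEK11	nucleus	Enzyme	Serine/threonine kinase
NR3C1	nucleus	Receptor	Ligand-dependent nuclear receptor
NTRK1	plasma membrane	Enzyme	Tyrosine kinase
PARP1	nucleus	Enzyme	Polymerase
PARP2	nucleus	Enzyme	Polymerase
PARP3	nucleus	Enzyme	Polymerase
PDCD1	plasma membrane	Receptor	Transmembrane receptor
PDGFRA	plasma membrane	Enzyme	Tyrosine kinase
PDGFRB	plasma membrane	Enzyme	Tyrosine kinase
PGF	extracellular space	Growth factor	Growth factor
PIK3CD	cytoplasm	Enzyme	Phosphatidyl Inositol Kinases
PRLR	plasma membrane	Receptor	Transmembrane receptor
PSMB1	cytoplasm	Enzyme	Peptidase
PSMB10	cytoplasm	Enzyme	Peptidase
PSMB2	cytoplasm	Enzyme	Peptidase
PSMB5	cytoplasm	Enzyme	Peptidase
PSMB8	cytoplasm	Enzyme	Peptidase
PSMB9	cytoplasm	Enzyme	Peptidase
PSMD1	cytoplasm	Other	Other
PSMD2	cytoplasm	Other	Other
PTK6	nucleus	Enzyme	Tyrosine kinase
RAF1	cytoplasm	Enzyme	Serine/threonine kinase
RARA	nucleus	Receptor	Ligand-dependent nuclear receptor
RARB	nucleus	Receptor	Ligand-dependent nuclear receptor
RARG	nucleus	Receptor	Ligand-dependent nuclear receptor
RET	plasma membrane	Enzyme	Tyrosine kinase
RRM1	nucleus	Enzyme	Ribonucleotide diphosphate reductase
RXRA	nucleus	Receptor	Ligand-dependent nuclear receptor
RXRB	nucleus	Receptor	Ligand-dependent nuclear receptor
RXRG	nucleus	Receptor	Ligand-dependent nuclear receptor
SH2B3	plasma membrane	Other	Other
SIK1	nucleus	Enzyme	Serine/threonine kinase
SMO	plasma membrane	Receptor	G-protein coupled receptor
SSTR2	plasma membrane	Receptor	G-protein coupled receptor
SSTR5	plasma membrane	Receptor	G-protein coupled receptor
TEK	plasma membrane	Enzyme	Tyrosine kinase
TLR7	plasma membrane	Receptor	Transmembrane receptor
TLR8	plasma membrane	Receptor	Transmembrane receptor
TNFRSF8	plasma membrane	Receptor	Transmembrane receptor
TNFSF11	extracellular space	Cytokine	Cytokine
VEGFA	extracellular space	Growth factor	Growth factor
VEGFB	extracellular space	Growth factor	Growth factor
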