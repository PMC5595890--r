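gene_symbol	gene_name	refseq_id
ABAT	(4-)Aminobutyrate transaminase	NM_001127448.1
ACACA	Acetyl-CoA carboxylase alpha	NM_198834.2
ACACB	Acetyl-CoA carboxylase beta	NM_001093.3
ACLY	ATP citrate lyase	NM_001303275.1
ACO2	Acotinase 2	NM_001098.2
ACSS2	Acetyl-CoA synthetase	NM_001242393.1
ALDOA	Aldolase, fructose-bisphosphate A	NM_000034.3
ARHGAP26	Rho GTPase activating protein 26	NM_015071.4
ATG4A	Autophagy related 4 A, cysteine peptidase	NM_052936.3
ATP5A1	ATP synthase complex, F1-ATP synthase subunit	NM_001257335.1
ATP5C1	ATP synthase complex, F1-ATP synthase subunit	NM_001001973.1
BCAT1	Branched chain amino-acid transaminase 1, cytosolic	NM_001178094.1
BCAT2	Branched chain amino-acid transaminase 2, mitochondrial	NM_001284325.1
C12orf5	TP53-induced glycolysis regulatory phosphatase (TIGAR)	NM_020375.2
CA12	Carbonic anhydrase XII	NM_206925.2
CA9	Carbonic anhydrase IX	NM_001216.2
CBR1	Carbonyl reductase 1	NM_001286789.1
CBS	Cystathione beta-synthase	NM_000071.2
CHKA	Choline kinase alpha	NM_212469.1
CKB	Creatine kinase, braintype	NM_001823.4
CPT1A	Carnitine palmitoyltransferase	NM_001031847.2
CS	Citrate synthase	NM_004077.2
CYCS	Cytochrome C, somatic	NM_018947.5
D2HGDH	D-2-hydroxyglutarate dehydrogenase	NM_152783.4
EGLN1	Prolylhydroxylase	NM_022051.2
ENO1	Enolase 1 (alpha)	NM_001428.3
EPAS1	Hypoxia-inducible factor 2-alpha	NM_001430.4
FASN	Fatty acid synthase	NM_004104.4
FH	Fumarate hydratase	NM_000143.3
G6PC	Glucose-6-phosphatase, catalytic subunit	NM_000151.3
G6PD	Glucose-6-phosphate dehydrogenase	NM_000402.4
GAD1	Glutamate decarboxylase	NM_000817.2
GAPDH	Glyceraldehyde-3-phosphate dehydrogenase	NM_002046.5
GCLC	Glutamate cysteine ligase	NM_001498.3
GCLM	Glutamate cysteine ligase	NM_001308253.1
GFPT1	Fructose-6-phosphate amido-transferase	NM_001244710.1
GLDC	Glycine dehydrogenase	NM_000170.2
GLS	Glutaminase	NM_001256310.1
GLUD1	Glutamate dehydrogenase 1	NM_005271.3
GLUD2	Glutamate dehydrogenase 2	NM_012084.3
GLUL	Glutamine synthetase	NM_001033056.3
GOT1	Glutamate oxaloacetate transaminase	NM_002079.2
GPI	Glucose-6-phosphate isomerase	NM_001289789.1
GPI	Phosphoglucose isomerase	NM_001289790.1
GPT	Glutamate pyruvate transaminase	NM_005309.2
GSS	Glutathione synthetase	NM_000178.2
HIF1A	Hypoxia-inducible factor 1-alpha	NM_001530.3
HK1	Hexokinase 1	NM_000188.2
HK2	Hexokinase 2	NM_000189.4
HK3	Hexokinase 3	NM_002115.2
IDH1	Isocitrate dehydrogenase 1 (NADP+), soluble	NM_005896.3
IDH2	Isocitrate dehydrogenase 2 (NADP+), mitochondrial	NM_002168.3
IDH3A	Isocitrate dehydrogenase 3, mitochondrial, alpha	NM_005530.2
IDH3B	Isocitrate dehydrogenase 3, mitochondrial, beta	NM_006899.3
IDH3G	Isocitrate dehydrogenase 3, mitochondrial, gamma	NM_174869.2
L2HGDH	L-2-hydroxyglutarate dehydrogenase	NM_024884.2
LDHA	Lactate dehydrogenase A	NM_001135239.1
LDHB	Lactate dehydrogenase B	NM_001174097.2
MAPK8	Mitogen-activated protein kinase 8	NM_001278547.1
MDH1	Malate dehydrogenase 1	NM_001199111.1
MDH2	Malate dehydrogenase 2	NM_001282403.1
MYC	V-myc avian myelocytomatosis viral oncogene homolog	NM_002467.4
NAMPT	Nicotinamide phosphoribosyltransferase	NM_005746.2
NAPRT1	Nicotinate phosphoribosyltransferase	NM_145201.5
NOX1	NADPH oxidase 1	NM_007052.4
NOX3	NADPH oxidase 3	NM_015718.2
NOX4	NADPH oxidase 4	NM_016931.4
NQO1	NAD(P)H dehydrogenase, quinone 1	NM_000903.2
OGDH	Oxoglutarate (alpha-ketoglutarate) dehydrogenase	NM_001003941.2
PARP1	Poly (ADP-ribose) polymerase 1	NM_001618.3
PC	Pyruvate carboxylase	NM_000920.3
PDHA1	Pyruvate dehydrogenase alpha 1	NM_000284.3
PDK1	Pyruvate dehydrogenase kinase 1	NM_001278549.1
PFKFB1	Phosphofructokinase 2, PFKFB1	NM_001271805.1
PFKM	Phosphofructokinase 1, PFKM	NM_001166686.1
PGAM1	Phosphoglycerate mutase 1	NM_002629.3
PGD	Phosphogluconate dehydrogenase	NM_002631.3
PGK1	Phosphoglycerate kinase 1	NM_000291.3
PGK2	Phosphoglycerate kinase 2	NM_138733.4
PKM	Pyruvate kinase, muscle	NM_001206796.2
PRDX1	Peroxiredoxin 1	NM_001202431.1
PRKAA1	AMP-activated protein kinase, catalytic subunit alpha-1	NM_006251.5
PRKAA2	AMP-activated protein kinase, catalytic subunit alpha-2	NM_006252.3
RPIA	Ribose 5-phosphate isomerase A	NM_144563.2
SDHA	Succinate dehydrogenase complex, subunit A	NM_001294332.1
SDHB	Succinate dehydrogenase complex, subunit B	NM_003000.2
SDHC	Succinate dehydrogenase complex, subunit C	NM_003001.3
SDHD	Succinate dehydrogenase complex, subunit D	NM_003002.3
SLC16A1	Monocarboxylate transporter 1	NM_001166496.1
SLC16A3	Monocarboxylate transporter 4	NM_001206952.1
SLC16A7	Monocarboxylate transporter 2	NM_001270622.1
SLC1A2	Glutamate transporter, glial high affinity 2	NM_001195728.2
SLC25A5	Adenine nucleotide translocase 2	NM_001152.4
SLC2A1	Glucose transporter 1	NM_006516.2
SLC2A3	Glucose transporter 3	NM_006931.2
SLC5A1	Sodium glucose cotransporter	NM_001256314.1
SLC7A1	Cationic amino acid transporter, y+ system	NM_003045.4
SLC9A1	Na+/H+ proton antiporter	NM_003047.4
SOD1	Superoxide dismutase 1	NM_000454.4
SOD2	Superoxide dismutase 2, mitochondrial	NM_000636.2
TALDO1	Transaldolase	NM_006755.1
TP53I3	Tumor protein p53 inducible protein 3	NM_004881.4
TXN	Thioredoxin	NM_001244938.1
VHL	Von Hippel Lindau	NM_198156.2
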