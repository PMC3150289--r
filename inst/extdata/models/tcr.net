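# TCR/CD4/CD28 signaling network (early and late horizons), including the
# PAG/CSK/LCKP1/FYN negative feedback loop compensated by the TCRB input.
# 106 components, 103 implication clauses.
model TCR
node TCRLIG input "peptide/MHC ligand engaging the TCR"
node CD4 input "CD4 co-receptor engaged"
node CD8 input "CD8 co-receptor engaged"
node CD28 input "CD28 engaged by CD80/CD86"
node CD45 input "CD45 phosphatase active (constitutive)"
node CAMP input "elevated cytosolic cAMP"
node CTLA4 input "CTLA-4 engaged (inhibitory)"
node CCBLR input "c-Cbl at the receptor complex"
node AKAP79 input "AKAP79 anchoring calcineurin (inhibitory)"
node DGKA input "diacylglycerol kinase alpha active (DAG turnover)"
node CBLB input "Cbl-b ubiquitin ligase active (inhibitory)"
node LIME input "LIME transmembrane adaptor (constitutive)"
node SIT input "SIT transmembrane adaptor (constitutive)"
node UNC119 input "Unc119 Lck chaperone (constitutive)"
node RACK1 input "RACK1 scaffold (constitutive)"
node GRAP input "Grap adaptor (constitutive)"
node TCRB internal "TCR engaged (bound) by ligand"
node PAG internal "PAG/Cbp phosphorylated, recruiting Csk"
node CSK internal "Csk active at the membrane"
node LCKP1 internal "Lck phosphorylated on the activating tyrosine (Y394)"
node LCKP2 internal "Lck phosphorylated on the inhibitory tyrosine (Y505)"
node FYN internal "Fyn kinase active"
node TCRP internal "TCR ITAMs phosphorylated"
node ZAP70 internal "ZAP-70 recruited to ITAMs and active"
node CCBLP1 internal "c-Cbl phosphorylated (receptor downregulation)"
node ABL internal "Abl kinase active"
node TEC internal "Tec kinase active"
node RLK internal "Rlk/Txk kinase active"
node TRIM internal "TRIM adaptor phosphorylated"
node LAT internal "LAT phosphorylated on distal tyrosines"
node GADS internal "Gads recruited to LAT"
node SLP76 internal "SLP-76 recruited via Gads and phosphorylated"
node NCK internal "Nck recruited to the LAT/SLP-76 complex"
node ITK internal "Itk recruited and active"
node PLCG1 internal "PLC-gamma-1 phosphorylated and active"
node DAG internal "diacylglycerol generated"
node IP3 internal "IP3 generated"
node ITPR internal "IP3 receptor channels open"
node CA internal "cytosolic calcium elevated"
node CALM internal "calmodulin loaded with calcium"
node CALCIN internal "calcineurin phosphatase active"
node CABIN1 internal "Cabin1 phosphorylated (calcineurin modulation)"
node CAMK4 internal "CaMKIV active"
node CREB output "CREB phosphorylated"
node NFAT output "NFAT dephosphorylated and nuclear"
node PKCTHETA internal "PKC-theta recruited to the immune synapse and active"
node CARMA1 internal "CARMA1 scaffold recruited"
node BCL10 internal "Bcl10 in the CBM complex"
node MALT1 internal "MALT1 in the CBM complex"
node TAK1 internal "TAK1 kinase active"
node IKK internal "IKK complex active"
node IKB internal "IkB phosphorylated and degraded"
node NFKB output "NF-kB translocated to the nucleus"
node RASGRP1 internal "RasGRP1 recruited via DAG and active"
node GRB2 internal "Grb2 adaptor recruited"
node SOS internal "SoS exchange factor recruited"
node RAS internal "Ras loaded with GTP"
node RAF internal "Raf-1 kinase active"
node MEK internal "MEK1/2 phosphorylated"
node ERK internal "ERK1/2 phosphorylated on T202/Y204"
node EGR1 output "Egr-1 expressed"
node FOS internal "c-Fos expressed"
node JUN internal "c-Jun phosphorylated"
node JUNB internal "JunB expressed"
node AP1 output "AP-1 transcriptional activity"
node GAB2 internal "Gab2 scaffold phosphorylated"
node SHP2 internal "SHP2 recruited to Gab2"
node PI3K internal "class IA PI3-kinase recruited and active"
node AKT internal "AKT phosphorylated on S473"
node COT internal "Cot/Tpl2 kinase active"
node VAV1 internal "Vav1 exchange factor active"
node VAV3 internal "Vav3 exchange factor active"
node RAC internal "Rac1 loaded with GTP"
node CDC42 internal "Cdc42 loaded with GTP"
node WASP internal "WASp activated"
node WAVE2 internal "WAVE2 activated"
node ARP23 internal "Arp2/3 complex nucleating actin"
node ACTIN internal "actin polymerization at the synapse"
node HPK1 internal "HPK1 recruited to the LAT complex and active"
node MEKK1 internal "MEKK1 kinase active"
node MEKK4 internal "MEKK4 kinase active"
node MLK3 internal "MLK3 kinase active"
node MKK4 internal "MKK4 active"
node MKK7 internal "MKK7 active"
node MKK3 internal "MKK3 active"
node MKK6 internal "MKK6 active"
node JNK internal "JNK phosphorylated on T183/Y185"
node P38 internal "p38 MAPK phosphorylated on T180/Y182"
node DLGH1 internal "Dlgh1 scaffold engaged (alternative p38 route)"
node SHP1 internal "SHP1 phosphatase active at the receptor (feedback)"
node SHIP1 internal "SHIP1 recruited and active"
node DOK1 internal "Dok-1 phosphorylated"
node RASA1 internal "p120 RasGAP recruited"
node FYB internal "ADAP/Fyb phosphorylated"
node SKAP55 internal "SKAP55 in the ADAP complex"
node RAP1 internal "Rap1 loaded with GTP"
node RIAM internal "RIAM recruited by Rap1"
node TALIN internal "talin bound to integrin tails"
node LFA1 output "LFA-1 in the high-affinity conformation"
node ADHESION output "integrin-mediated adhesion"
node PKA internal "protein kinase A active"
node PDE4B internal "PDE4B phosphodiesterase recruited (cAMP turnover)"
node IL2GENE internal "IL-2 gene transcribed"
node IL2SEC output "IL-2 secreted"
node IL2RAGENE output "IL-2R alpha chain (CD25) gene transcribed"
node NUR77 output "Nur77 expressed"
TCRB = TCRLIG
PAG = FYN & !TCRB @early
PAG = FYN @late
CSK = PAG
CSK = PKA
LCKP1 = CD4 & CD45 & !CAMP & !CSK & !SHP1
LCKP1 = CD8 & CD45 & !CAMP & !CSK & !SHP1
LCKP2 = CSK
FYN = LCKP1 & TCRB
FYN = PAG & TCRB
TCRP = LCKP1 & TCRB
TCRP = FYN & TCRB
ZAP70 = LCKP1 & TCRP & !CBLB & !CCBLP1
CCBLP1 = CCBLR & ZAP70 @late
ABL = ZAP70
TEC = LCKP1
RLK = LCKP1
TRIM = LCKP1
LAT = ZAP70
GADS = LAT
SLP76 = GADS
NCK = LAT & SLP76
ITK = LCKP1 & SLP76
PLCG1 = ITK & LAT
PLCG1 = LAT & TEC
PLCG1 = LAT & RLK #quality=potential
DAG = PLCG1 & !DGKA
IP3 = PLCG1
ITPR = IP3
CA = ITPR
CALM = CA
CALCIN = CALM & !AKAP79
CABIN1 = CAMK4
CAMK4 = CALM
CREB = CAMK4
NFAT = CALCIN
PKCTHETA = DAG & SLP76
CARMA1 = PKCTHETA
BCL10 = CARMA1
MALT1 = BCL10
TAK1 = MALT1
IKK = BCL10 & CARMA1 & MALT1 & TAK1
IKB = IKK
NFKB = IKB
RASGRP1 = DAG & PKCTHETA
GRB2 = LAT
SOS = GRB2
RAS = GRB2 & SOS
RAS = RASGRP1
RAF = RAS
MEK = RAF
ERK = MEK & PKCTHETA
EGR1 = ERK
FOS = ERK
JUN = JNK
JUNB = JNK
AP1 = FOS & JUN
GAB2 = GRB2
SHP2 = GAB2
PI3K = CD28 & LCKP1 & !CTLA4
PI3K = GAB2 & LCKP1
AKT = PI3K
COT = AKT
VAV1 = PI3K & ZAP70
VAV3 = ZAP70
RAC = VAV1
RAC = VAV3
CDC42 = VAV1
WASP = CDC42 & NCK
WAVE2 = RAC
ARP23 = WASP
ACTIN = ARP23
HPK1 = LAT & SLP76
MEKK1 = HPK1
MEKK1 = RAC
MEKK4 = CDC42 & RAC
MLK3 = RAC
MKK4 = MEKK1
MKK7 = MEKK1
MKK7 = MLK3
MKK3 = MEKK4
MKK6 = MEKK4
JNK = MKK4 & MKK7
P38 = MKK3 & MKK6
P38 = DLGH1 #quality=potential
DLGH1 = LCKP1 & ZAP70
SHP1 = LCKP1 & !ERK @late
SHIP1 = LAT
DOK1 = SHIP1
RASA1 = DOK1
FYB = FYN & SLP76
SKAP55 = FYB
RAP1 = SKAP55
RIAM = RAP1
TALIN = RIAM
LFA1 = TALIN
ADHESION = ACTIN & LFA1
PKA = CAMP
PDE4B = ERK
IL2GENE = AP1 & NFAT & NFKB
IL2SEC = IL2GENE
IL2RAGENE = NFAT & NFKB
NUR77 = NFAT
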