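# IL-2 receptor signaling network as assembled from the literature, before
# the validation experiments in human T-cell blasts. 68 components, 69
# implication clauses. Differences from the validated revision: the
# (potential) SFK->STAT links are still present, PI3K is activated directly
# at the receptor, ERK depends only on MEK, JNK is activated directly by
# SFKs, and LAT / FYN / PLD / DAG / nPKC / p38 are unregulated grey nodes
# (inputs from other receptors or regulation not known).
model IL2R_initial
node IL2 input "interleukin-2 bound to the receptor"
node IL2RA input "IL-2R alpha chain (CD25) expressed"
node IL2RB input "IL-2R beta chain expressed"
node IL2RG input "common gamma chain expressed"
node CAMP input "elevated cytosolic cAMP"
node PTEN input "PTEN lipid phosphatase active"
node LAT input "LAT phosphorylated (regulation by IL-2 not known)"
node FYN input "Fyn kinase active (regulation by IL-2 not known)"
node PLD input "phospholipase D active (regulation by IL-2 not known)"
node DAG input "diacylglycerol generated (regulation by IL-2 not known)"
node NPKC input "novel PKC isoforms active (regulation by IL-2 not known)"
node P38 input "p38 MAPK phosphorylated (regulation by IL-2 not known)"
node JAK3 internal "JAK3 active at the gamma chain"
node JAK1 internal "JAK1 recruited to the phosphorylated beta chain and active"
node IL2RBP internal "IL-2R beta chain phosphorylated on cytoplasmic tyrosines"
node SHC internal "Shc recruited to the beta chain and phosphorylated"
node LCKP1 internal "Lck phosphorylated on the activating tyrosine (Y394)"
node SYK internal "Syk kinase active"
node PI3K internal "class IA PI3-kinase recruited and active"
node PIP3 internal "PIP3 levels increased at the membrane"
node PDK1 internal "PDK1 recruited via PIP3"
node AKT internal "AKT phosphorylated on S473"
node GRB2 internal "Grb2 adaptor recruited"
node SOS internal "SoS exchange factor recruited"
node RAS internal "Ras loaded with GTP"
node RAF internal "Raf-1 kinase active"
node MEK internal "MEK1/2 phosphorylated"
node ERK internal "ERK1/2 phosphorylated on T202/Y204"
node GAB2 internal "Gab2 scaffold phosphorylated"
node SHP2 internal "SHP2 recruited to Gab2"
node JNK internal "JNK phosphorylated on T183/Y185"
node STAT1 internal "STAT1 phosphorylated"
node STAT3 internal "STAT3 phosphorylated on Y705"
node STAT5 internal "STAT5 phosphorylated on Y694"
node STAT1DIM internal "STAT1 dimers translocated to the nucleus"
node STAT3DIM internal "STAT3 dimers translocated to the nucleus"
node STAT5DIM internal "STAT5 dimers translocated to the nucleus"
node SHP1 internal "SHP1 recruited to the receptor complex (desensitization)"
node SOCS1 internal "SOCS1 expressed (negative feedback)"
node SOCS3 internal "SOCS3 expressed (negative feedback)"
node CIS internal "CIS expressed (negative feedback)"
node MTOR internal "mTORC1 active"
node P70S6K internal "p70 S6 kinase active"
node S6 output "ribosomal protein S6 phosphorylated"
node EIF4E output "eIF4E released from 4E-BP1"
node GSK3B internal "GSK3beta phosphorylated (inactivated)"
node BAD internal "BAD phosphorylated (pro-survival)"
node FOXO1 internal "FoxO1 phosphorylated and exported from the nucleus"
node MDM2 internal "MDM2 phosphorylated"
node IKK internal "IKK complex active"
node IKB internal "IkB phosphorylated and degraded"
node NFKB output "NF-kB translocated to the nucleus"
node FOS internal "c-Fos expressed"
node ELK1 output "Elk-1 phosphorylated"
node RSK internal "p90 RSK active"
node JUN internal "c-Jun phosphorylated"
node ATF2 output "ATF-2 phosphorylated"
node MK2 output "MAPKAPK2 active"
node AP1 output "AP-1 transcriptional activity"
node MYC output "c-Myc expressed"
node BCL2 output "Bcl-2 expressed"
node BCLXL output "Bcl-xL expressed"
node CYCLIND2 output "cyclin D2 expressed"
node CYCLIND3 output "cyclin D3 expressed"
node PIM1 output "Pim-1 kinase expressed"
node P27KIP1 internal "p27Kip1 phosphorylated (targeted for degradation)"
node CRKL internal "CrkL adaptor phosphorylated"
node BLIMP1 output "Blimp-1 expressed"
JAK3 = IL2 & IL2RA & IL2RB & IL2RG
JAK1 = IL2RB & JAK3
IL2RBP = JAK1 & JAK3
SHC = IL2RBP
LCKP1 = IL2RBP & !SHP1
SYK = IL2RBP
PI3K = IL2RBP & !CAMP
PI3K = GAB2 & !CAMP
PIP3 = PI3K & !PTEN
PDK1 = PIP3
AKT = PDK1 & PIP3
GRB2 = SHC
SOS = GRB2
RAS = SOS
RAF = RAS
MEK = RAF
ERK = MEK
GAB2 = GRB2
GAB2 = SHC
SHP2 = GAB2 & !ERK
JNK = LCKP1
STAT1 = JAK1 & JAK3
STAT3 = JAK1 & JAK3
STAT3 = LCKP1 #quality=potential
STAT5 = JAK1 & JAK3
STAT5 = LCKP1 #quality=potential
STAT1DIM = STAT1
STAT3DIM = STAT3
STAT5DIM = STAT5
SHP1 = IL2RBP @late
SOCS1 = STAT5DIM @late
SOCS3 = STAT3DIM @late
SOCS3 = STAT5DIM @late
CIS = STAT5DIM @late
MTOR = AKT
P70S6K = MTOR & PDK1
S6 = P70S6K
S6 = RSK
EIF4E = MTOR
GSK3B = AKT
BAD = AKT
FOXO1 = AKT
MDM2 = AKT #quality=potential
IKK = AKT
IKK = NPKC
IKB = IKK
NFKB = IKB
FOS = ERK
FOS = STAT3DIM
ELK1 = ERK
RSK = ERK
JUN = JNK
ATF2 = P38
MK2 = P38
AP1 = FOS & JUN
MYC = STAT3DIM
MYC = STAT5DIM
BCL2 = STAT3DIM
BCL2 = STAT5DIM
BCLXL = STAT5DIM
BCLXL = NFKB #quality=potential
CYCLIND2 = MYC
CYCLIND2 = STAT5DIM
CYCLIND3 = STAT5DIM
PIM1 = STAT5DIM
P27KIP1 = AKT
CRKL = IL2RBP #quality=potential
BLIMP1 = STAT3DIM
BLIMP1 = STAT5DIM
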