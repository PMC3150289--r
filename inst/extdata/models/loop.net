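# The PAG/CSK/LCKP1/FYN negative feedback loop, compensated by the TCRB
# input to the clause producing PAG. With TCRB = 1 the unique feasible state
# is PAG = 0, CSK = 0, LCKP1 = 1, FYN = 1; with TCRB = 0 the early system is
# infeasible and each of the four implications is a singleton minimal
# intervention.
model loop
node TCRB input "TCR engaged by ligand"
node PAG internal "PAG/Cbp phosphorylated, recruiting Csk"
node CSK internal "Csk active at the membrane"
node LCKP1 internal "Lck phosphorylated on the activating tyrosine"
node FYN internal "Fyn kinase active"
CSK = PAG
LCKP1 = !CSK
FYN = LCKP1
PAG = FYN & !TCRB @early
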