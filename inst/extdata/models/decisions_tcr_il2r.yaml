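# Expert decisions for merging the TCR and IL-2R parent networks.
# Every conflicted component is resolved by the union of both parents'
# activating routes: each route is experimentally supported in its own
# receptor context, and keeping both preserves the recovery of the
# single-receptor activation patterns in the child.
- consequent: LCKP1
  resolution: union
  justification: >-
    Both receptors activate Lck; whether a common pool is used is an open
    experimental question, so both activation routes are retained. SHP1
    inhibition applies to Lck itself and appears in both clauses.
- consequent: FYN
  resolution: union
  justification: >-
    Fyn is activated at the TCR (via Lck or PAG-bound pools) and at the
    phosphorylated IL-2R beta chain; receptor-specific routes retained.
- consequent: LAT
  resolution: union
  justification: >-
    ZAP-70 phosphorylates LAT downstream of the TCR; IL-2 induced LAT
    phosphorylation is SFK-dependent. The IL-2R clause may be a
    simplification omitting intermediate steps (refinement candidate).
- consequent: DAG
  resolution: union
  justification: >-
    The receptors use different routes to generate DAG (PLC-gamma-1 versus
    PLD); both DAG species are assumed competent to activate PKCs.
- consequent: GRB2
  resolution: union
  justification: >-
    Grb2 is recruited to LAT at the TCR and to Shc at the IL-2R;
    receptor-specific adaptors, no contradiction.
- consequent: GAB2
  resolution: union
  justification: >-
    Gab2 is recruited via Grb2 in both pathways and additionally via Shc at
    the IL-2R.
- consequent: SHP2
  resolution: union
  justification: >-
    The IL-2R clause adds NOT ERK: ERK can prevent SHP2 recruitment to Gab2.
    Whether ERK always inhibits SHP2 or only in IL-2R signaling is untested
    in the TCR context; both clauses are retained pending experiment.
- consequent: PI3K
  resolution: union
  justification: >-
    PI3K is a likely cross-talk element: CD28/Lck- and Gab2-dependent
    recruitment at the TCR, SFK- and JAK-dependent activation at the IL-2R,
    with cAMP inhibition. All routes converge on the same class IA enzyme.
- consequent: AKT
  resolution: union
  justification: >-
    The TCR description (AKT downstream of PI3K) is a simplification of the
    PIP3/PDK1 mechanism spelled out in the IL-2R parent.
- consequent: RAS
  resolution: union
  justification: >-
    Grb2/SoS acts at both receptors; RasGRP1 is TCR-specific and has been
    excluded from IL-2R signaling.
- consequent: ERK
  resolution: union
  justification: >-
    ERK requires MEK in both parents; the IL-2R clause adds the JAK, PI3K
    and novel-PKC requirements, and the TCR clause the PKC-theta
    requirement. PKC-theta is one of the novel PKCs (isoform question), and
    the largely common ERK pathway suggests shared kinase dependencies.
- consequent: JNK
  resolution: union
  justification: >-
    The TCR parent resolves JNK activation to the MKK4/MKK7 module; the
    IL-2R statement (JAKs, PI3K) is not wrong but less precise - the
    SFK/PI3K-dependent routes of the TCR network are themselves upstream of
    MKK4/7. Retained pending identification of the IL-2R route.
- consequent: P38
  resolution: union
  justification: >-
    p38 activation is known in detail for the TCR (MKK3/6, alternative
    Dlgh1 route) but only at JAK resolution for the IL-2R.
- consequent: FOS
  resolution: union
  justification: >-
    c-Fos is induced by ERK in both pathways and additionally by STAT3
    downstream of the IL-2R.
- consequent: IKK
  resolution: union
  justification: >-
    The CBM/TAK1 route is TCR-specific; AKT- and nPKC-dependent IKK
    activation at the IL-2R is retained as a parallel input.
- consequent: SHP1
  resolution: union
  justification: >-
    SHP1 is a shared late negative regulator and a candidate mediator of
    cross-inhibition: activated Lck induces it at the TCR (unless protected
    by ERK), receptor recruitment induces it at the IL-2R.
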