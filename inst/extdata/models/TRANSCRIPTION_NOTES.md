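# Transcription notes for the bundled models

The bundled TCR, IL-2R and merged networks are **synthetic reconstructions**
of published curated T-cell signaling models. The clause-level supplementary
listings of the original study are distributed only as PDF attachments and
are not machine-readable here, so the networks were re-assembled from the
published figure legends, the worked examples in the methods narrative, and
the described experimental revisions, with the following priorities:

1. published component / clause totals (IL-2R initial 68 components and
   69 clauses; IL-2R validated 68 and 73; merged child 150 and 167);
2. the explicitly printed clauses and examples (the PAG / CSK / LCKP1 / FYN
   negative feedback loop with its TCRB compensation; the GAB2 -> SHP2
   versus NOT ERK AND GAB2 -> SHP2 conflict; direct SFK -> JNK activation in
   the initial IL-2R model; PKC-theta versus novel-PKC isoform resolution);
3. the described validation revisions (SFK->STAT links removed; PI3K
   downstream of SFKs and JAKs; ERK requiring JAKs AND PI3K AND nPKCs; JNK
   requiring JAKs AND PI3K; LAT phosphorylation added);
4. standard pathway topology from the signaling literature for the
   remaining interactions.

Consequences:

- Component inventories and pathway structure are faithful at module level,
  but individual clauses away from the documented examples are plausible
  reconstructions, not verbatim transcriptions. Counts match the published
  totals by construction; clause-for-clause identity with the original
  supplementary tables cannot be guaranteed.
- `merged_tcr_il2r.net` is not hand-written: it is the canonical
  serialization of `merge_networks(TCR, IL2R_validated)` under the bundled
  isoform hierarchy and decisions file, and is regenerated (and checked) by
  the test suite.
- A handful of constitutive or annotation-only nodes (e.g. LIME, SIT,
  UNC119, RACK1, GRAP) are carried in the component inventory without wired
  interactions, mirroring how curated component lists include molecules
  whose regulation is below the evidence standard.
- Sequential stimulation (IL-2 pre-stimulation followed by TCR engagement)
  reproduces the published qualitative prediction on the reconstruction:
  ERK and AKT remain inactive in every feasible state while STAT3/STAT5
  activation persists.
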