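# signalogic

Logical modeling, IFF-SAT analysis and semi-automated merging of receptor
signaling networks, with bundled transcriptions of curated T-cell receptor
(TCR) and interleukin-2 receptor (IL-2R) models.

## The problem and the formalism

Curated signaling pathways are collections of causal statements such as
"*MEK activates ERK*" or "*STAT3 or STAT5 induce Blimp-1*". `signalogic`
represents each statement as an **implication formula**

```
A1 AND ... AND Ak -> B        (literals Ai may be negated: NOT CSK -> LCKP1)
```

tagged with a **time horizon** — `early` (ascending flank of a transient
signal, activators dominate), `late` (negative regulators dominate), or
`permanent` (both). A component that has a regulator cannot change state
without a reason, so for one horizon all statements with the same right-hand
side are collected and strengthened to the **if-and-only-if (IFF) clause**

```
(A1 OR ... OR An) <-> B
```

The conjunction *S* of all IFF clauses of a horizon defines the admissible
states of the network: every satisfying assignment of *S* is one possible
state. Questions about the biology become satisfiability queries:

* **Feasibility / prediction** — given a *fixation pattern* (a partial
  ON/OFF assignment encoding stimuli and readouts), does a satisfying total
  state exist, and what do all such states agree on?
* **Minimal interventions** — if a fixation is infeasible, which
  subset-minimal sets of implications must be relaxed to restore
  feasibility? These point at modeling errors, inconsistent literature, or
  negative feedback loops acting on the late time scale.
* **Infeasible cores** — minimal unsatisfiable subsystems; a core whose
  clauses form a cycle with an odd number of inhibitions is a negative
  feedback loop (the PAG/CSK/LCKP1/FYN loop of TCR signaling is the
  canonical example, bundled as the `loop` model).
* **Model merging** — two *parent* networks are standardized, unioned and
  checked into a *child*; shared components with differing regulation raise
  classified conflicts (overlapping clauses, disjoint clauses,
  refinement/simplification, isoform resolution) that expert decisions
  resolve, with provenance tracked per clause.
* **Logical projection** — re-express the feasible states restricted to a
  component subset as a smaller network (exact, via prime-implicant DNF
  synthesis; refused explicitly when no exact representation exists).

A built-in DPLL solver (Tseitin CNF encoding, one auxiliary variable per
DNF disjunct) powers all queries; an independent truth-table enumerator
(`brute_force_states()`) serves as the reference on small systems.

## Worked example: the compensated negative feedback loop

```r
library(signalogic)
loop <- load_model("loop")   # PAG <-> CSK -| LCKP1 -> FYN -> PAG, input TCRB
is_feasible(loop, c(TCRB = 1))
#> feasible
#>   ON : FYN, LCKP1, TCRB
```

With the TCR engaged the loop is *compensated*: the unique state has
`PAG = 0, CSK = 0, LCKP1 = 1, FYN = 1` — active Lck and Fyn, with the
PAG/Csk brake released. Without the stimulus the early system is
unsatisfiable, and the package explains why:

```r
is_feasible(loop, c(TCRB = 0))
#> infeasible
#> infeasible core: 4 clause(s) [CSK, FYN, LCKP1, PAG] + fixation {TCRB=0}
#>   cycle: CSK -> LCKP1 -> FYN -> PAG -> CSK (negative feedback)
#>   - candidate for reclassification as late implication
minimal_interventions(loop, "early", c(TCRB = 0))
#> four singleton sets, one per loop implication
```

## Bundled models and the cross-talk prediction

| model | components | clauses |
|---|---|---|
| `IL2R_initial` | 68 | 69 |
| `IL2R_validated` | 68 | 73 |
| `TCR` | 106 | 103 |
| `MERGED` | 150 | 167 |

`MERGED` is reproduced exactly by
`merge_networks(load_model("TCR"), load_model("IL2R_validated"),
bundled_isoforms(), bundled_decisions())`. The models are reconstructions
from published figure legends; see
`inst/extdata/models/TRANSCRIPTION_NOTES.md` for their provenance and
limits.

Sequential stimulation — IL-2 pre-stimulation (late phase) followed by TCR
engagement — is the headline prediction:

```r
net <- load_model("MERGED")
stim <- c(IL2 = 1, IL2RA = 1, IL2RB = 1, IL2RG = 1,
          TCRLIG = 1, CD4 = 1, CD28 = 1, CD45 = 1)
predict_sequential(net, stim, first = "IL2R",
                   readouts = c("ERK", "AKT", "STAT5", "LAT"))
#>   component state
#> 1       ERK   OFF
#> 2       AKT   OFF
#> 3     STAT5    ON
#> 4       LAT   OFF
```

ERK and AKT remain inactive in **every** feasible state (the late IL-2R
phosphatase feedback holds Lck, PI3K and the MEK/ERK input off), while
STAT5 signaling persists — the desensitization pattern expected for IL-2
pre-treated T-cell blasts.

## Command line

```sh
signalogic check loop --fix TCRB=1                 # exit 0, prints witness
signalogic check loop --fix TCRB=0                 # exit 1, prints core
signalogic predict MERGED --stimulus IL2=1,IL2RA=1,IL2RB=1,IL2RG=1,TCRLIG=1,CD4=1,CD28=1,CD45=1 \
          --first IL2R --readouts ERK,AKT,STAT5
signalogic merge tcr.net il2r.net --decisions dec.yaml -o child.net --report report.yaml
signalogic project chain.net --keep A,C
signalogic generate --n 12 --m 14 --seed 1 -o random.net
```

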