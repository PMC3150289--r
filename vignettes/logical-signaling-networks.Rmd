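---
title: "Logical signaling networks: IFF systems, interventions and model merging"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Logical signaling networks: IFF systems, interventions and model merging}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(signalogic)
```

## The model

A logical network assigns one Boolean variable to each signaling component;
the meaning of the ON state is fixed per component (an amount increase for a
second messenger, a phosphorylation for a kinase, a recruitment for an
adaptor) and recorded in its `interpretation`. Knowledge statements are
implication formulas — a conjunction of possibly negated literals activating
one consequent. Two assumptions turn a pile of implications into a state
space:

1. **No change without a reason.** A regulated component is ON exactly when
   at least one of its activating conditions holds, so the collected
   statements `A1 OR ... OR An -> B` are strengthened to the IFF clause
   `(A1 OR ... OR An) <-> B`. Inputs (components with no regulator) are
   unconstrained.
2. **Two time scales.** The formalism does not model kinetics; it
   discretizes a transient signal into an *early* horizon (activators
   dominate, negative feedbacks not yet engaged) and a *late* horizon
   (negative regulators dominate). Every implication carries `early`,
   `late`, or `permanent` validity; `compile_iff()` selects the horizon set
   and builds the clause system per phase. No synchronous or asynchronous
   update semantics is implied — a feasible assignment of the clause
   conjunction is a network state, nothing more.

A consequence of the per-phase selection: a component whose implications are
all out of phase (e.g. a purely late feedback queried at early times) has no
in-system regulator and becomes *free*, not forced OFF. Forcing it OFF would
manufacture a reason for a state that the phase's clauses cannot justify.
This choice propagates into predictions: early-phase queries on networks
with late feedbacks return state *sets* in which the feedback components
range over both values, and only readouts identical across all states are
firm predictions. `predict_summary()` decides ON/OFF/either per readout with
two satisfiability calls instead of enumeration.

## Solving

Each clause `B <-> D1 | ... | Dk` is translated to CNF with one auxiliary
variable per disjunct (`aux_j <-> Dj`, `B -> aux_1 | ... | aux_k`,
`aux_j -> B`); fixations are unit clauses. Since the auxiliaries are
functions of the component variables, enumerating CNF models projected to
components enumerates states without duplicates. The solver is a DPLL with
unit propagation; branching follows sorted component order with OFF tried
first, so enumeration is deterministic and lexicographic, and
`enumerate_states()` detects truncation by requesting one state beyond its
cap. At the scale of curated signaling models (the merged network compiles
to roughly 350 CNF variables and 900 clauses) this is instantaneous; the
design favors transparency and determinism over industrial solver
performance, and `brute_force_states()` provides an independent truth-table
reference for networks of at most 20 components.

Infeasibility analysis uses deletion-based minimal-unsatisfiable-subset
extraction over the soft items (one per IFF clause, one per fixation entry)
in a fixed order, so cores are reproducible. Multiple causes are found by
removing each core's items and re-extracting while the remainder is
infeasible, capped at 20 cores: disjoint conflicts are all reported, while
overlapping causes sharing a clause may be represented by a single core.
Core components are checked for directed cycles among the core's own
interactions; a cycle with an odd number of inhibitions is flagged as a
negative feedback loop and suggested for reclassification as late — the
diagnostic that originally separated the two time scales.

`minimal_interventions()` searches relaxation sets breadth-first by
cardinality (default cap 3, result cap 100) with superset pruning, which
guarantees subset-minimality and determinism; after removing a set's
implications the system is recompiled, so a consequent that loses all
in-phase activators becomes free. The search is exhaustive at curated-model
scale; it is quadratic-to-cubic in the clause count and is not intended for
genome-scale networks.

## Prediction conventions

In `predict()` the stimulus may fix input components only; unnamed inputs
default to OFF — the biological resting state, and the convention that makes
stimulus scenarios comparable across models. General fixations (clamping
internal readouts, knock-downs) go through `is_feasible()` /
`enumerate_states()`, where unfixed inputs stay free. Two open choices in
the two-time-scale formalism are exposed rather than decided:

* `inherit_early = TRUE` makes the late phase inherit every component value
  that is forced in the early phase under the same stimulus; the default
  (`FALSE`) solves the late system independently.
* `predict_sequential()` models "receptor 2 engaged while receptor 1 is in
  its late phase" by selecting the late horizon set for implications whose
  provenance includes the first receptor's parent model and the early set
  for implications exclusive to other parents (an implication carrying both
  provenances follows the late set). This per-implication selection is the
  package's reading of sequential stimulation; the formalism itself does
  not pin down a unique semantics.

On the bundled merged model, IL-2 pre-stimulation followed by TCR engagement
yields two feasible states (one free late-only TCR component), all with ERK
and AKT OFF and STAT3/STAT5 ON: the late IL-2R clauses force the
receptor-recruited phosphatase ON, which de-activates Lck in every clause
that could feed PI3K, the MEK/PKC route to ERK, and the PIP3/PDK1 route to
AKT, while JAK/STAT signaling has no SHP1 dependence and persists.

## Merging

`merge_networks()` automates what can be automated: component union with
provenance labels, deduplication of identical statements (provenance union),
and a conservative default — the union of both parents' activating DNFs —
for every conflict without an expert decision. Fully automatic merging can
do no better than this annotated union; the scientific content is in the
conflicts it surfaces, classified as:

* **A** — overlapping but non-identical left-hand sides (is the extra
  condition universal or receptor-specific?);
* **B** — disjoint left-hand sides (receptor-specific mediators, or
  cross-activation?);
* **C** — disjoint, but one parent's direct antecedent reaches the
  consequent through a directed path (length 2–10, positive interactions)
  in the other parent: a probable simplification omitting intermediates.
  The path cap is a practical bound, not a biological claim;
* **D** — antecedents related through an explicit isoform hierarchy
  (e.g. PKC-theta below the novel-PKC class). Automatic name-substring
  matching is deliberately not attempted.

Decisions (`union`, `keep_A`, `keep_B`, `replace_with`) are recorded with
justifications in a YAML file and replayed by `merge_networks()`; the merge
report serializes with stable key order so curation history diffs cleanly.
`verify_merge()` closes the loop: each parent's known activation pattern
must remain feasible in the child, and failures are routed to the
intervention search. Statements flagged `potential` (below the curation
evidence standard) are carried through unchanged and listed in the report;
they are not down-weighted, because the formalism has no weights.

## Projection

`project_network()` restricts the feasible-state set to a keep set and
re-expresses it as a network: components functionally determined by the
other kept components (on the observed states) get one clause; others become
inputs. Contexts never observed are don't-cares, filled deterministically —
OFF by default, re-pinned while spurious states remain. Right-hand sides are
minimized by Quine–McCluskey prime implicants with essential-first exact
cover (lexicographic tie-break; a deterministic greedy cover takes over
beyond 14 candidate implicants — determinism over optimality). Two refusals
are explicit, never silent: networks beyond the 20-component enumeration
guard, and relations that no one-clause-per-component system can express —
a hidden component can mediate a dependency (e.g. the projected relation
{00, 10, 11} over two components) in which neither component is a function
of the other, yet the pair is constrained; such a relation has no IFF
representation, which the don't-care refinement proves by exhausting its
freedom. Constant clauses (`B = 1`, `B = 0`) are permitted in projected
networks to pin components whose projected behavior is constant.

## The random-network generator

`generate_network()` exists so that every solver and merger property is
testable without external data. It wires the requested number of
implications over a random topological order (the permanent-horizon core is
acyclic) and lets late-horizon implications point backwards, creating
feedback loops — hence a supply of infeasible fixation patterns for
intervention tests. Defaults follow the bundled models' character: antecedent
conjunctions of at most 3 literals, and test families use negation
probabilities of 0.3–0.4 and late fractions of 0.2–0.3 — deliberately denser
than the curated networks (the merged model has about 7% negated literals
and 5% late clauses) so that feedback and inhibition are exercised hard. Identical configuration and seed give byte-identical files, and
generation restores the session RNG state.

What generated networks do *not* emulate: the scale-free hub structure,
coherent pathway modules and biologically meaningful feedback placement of
curated models. Passing the seeded equivalence properties therefore
demonstrates the correctness of the algorithms on arbitrary small logical
structures, not biological validity — that is what the bundled transcriptions
and their documented predictions are for.

## Test and verification sizes

The shipped test suite cross-checks the solver against exhaustive
enumeration on 100 seeded networks of 8–16 components (both phases), the
intervention search against exhaustive subset search (cardinality ≤ 3) on 50
seeded infeasible instances of 10 components, projection on 50 seeded
networks of 9 components with random keep sets, and disjoint-merge recovery
on 10 seeded parent pairs (15 combined components). These sizes keep
exhaustive reference enumeration exact; the package's own operations handle
the 150-component merged model directly.

## Known limitations

* No kinetics, no multi-valued logic, no trajectory or attractor
  computation: a state is a satisfying assignment, and the two horizons are
  the only temporal structure.
* Exact projection is limited to networks enumerable under the size guard
  and to relations expressible one-clause-per-component; both limits raise
  errors rather than approximate.
* MUS iteration reports at least one cause per independent conflict but is
  not guaranteed to list every overlapping cause.
* The bundled models are count-calibrated reconstructions (see
  `TRANSCRIPTION_NOTES.md`); analyses at single-clause resolution away from
  the documented examples inherit that uncertainty.
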