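---
title: "Bounded synthesis of proteomics tool pipelines"
author: "edamcompose"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Bounded synthesis of proteomics tool pipelines}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(edamcompose)
```

# The composition model

`edamcompose` treats a data-analysis pipeline as a word over a finite
alphabet of tools, together with the sequence of concrete data states it
induces. Three ingredients parameterise the search:

* **Taxonomy.** An is-a DAG over four branches (operation, data, format,
  topic). Multiple parents are allowed — ontologies of this kind are DAGs,
  not trees — and subsumption is reflexive–transitive reachability over
  all parents. The transitive closure is precomputed at load time, so
  subsumption queries during search are hash lookups. Identifiers are
  curie-like (`operation:3631`), case-sensitive, and must match
  `^(operation|data|format|topic):[0-9]+$`.

* **Tool annotations.** Each tool carries one or more operation concepts
  and exactly one input and one output port (a data concept plus one or
  more formats). The single-port restriction is what makes linear
  pipelining sound: a single data item flows through the chain. Tools with
  several declared output formats branch into one successor state per
  format, so solutions are *state-annotated* paths.

* **Specification.** An initial concrete state, a goal class (data concept
  and format concept, the format root meaning "any format"), a list of
  constraints, a length bound, and a mode: `shortest_only` keeps only the
  first length at which any solution exists; `up_to_bound` keeps all of
  them.

**Matching direction.** Specifications and annotations name *classes*;
states are *concrete*. A state `(d, f)` satisfies a declared port
`(D, {F...})` when `d` is a descendant-or-equal of `D` and `f` of some
declared `F`. The same direction applies to the goal. This is the only
direction that makes "any format" goals and class-level constraint fillers
meaningful, and it makes applicability monotone under ontology growth:
adding an is-a edge can only enable tools, never disable them (this is
property-tested).

# Constraints and monitors

Five natural-language templates cover the constraint vocabulary:
`use A`, `do not use A`, `use A only after B`,
`do not use A more than once`, `do not use A directly after A`.
Fillers resolve to either a concrete tool (matched by name) or an
operation class (matched against a tool's annotated operations under
subsumption; a tool's placement in the operation taxonomy beyond its
annotations plays no role). Labels are accepted in place of curies when
unambiguous.

Two readings of *"use A only after B"* are defensible: B immediately
before A, or B anywhere before A. The anywhere-before (weak-until) reading
is implemented: a trace violates the constraint only if some position
matches A with no *strictly earlier* position matching B, and B need not
occur at all when A never does. This reading keeps the bundled use-case
pipelines satisfiable (for example, validation runs two steps after the
database search in every enrichment pipeline) and treats a step matching
both A and B, with no earlier B, as a violation. The immediate-before
reading would change solution counts; it can be emulated by tightening
the domain model and is deliberately not a template.

Each constraint compiles to a deterministic, total, finite-state monitor:
2 states for `use`/`do not use`, 3 for the other forms, including an
explicit reject sink where one exists. Monitor inputs are per-step atom
truth values, which depend only on the tool, not on the position — so they
are precomputed per tool before the search. The equivalence between
monitor acceptance and the declarative trace semantics is the load-bearing
correctness property and is tested on thousands of random
constraint/trace pairs. The empty trace satisfies every form except `use`.

Global constraints live in the domain model and apply to every run. The
bundled model carries two: msconvert and idconvert must never run twice in
a row, which removes pointless chains of format conversions while still
allowing, e.g., a conversion to recur later in the pipeline.

# The search

Synthesis is breadth-first over the product of concrete data states and
the joint monitor state vector. Each layer deduplicates product nodes, so
the frontier never exceeds |data states| × Π(monitor states) entries per
layer; an explored-node counter in every `SolutionSet` lets callers verify
this bound. Successors entering any reject sink are pruned immediately —
sound because sinks are absorbing and non-accepting, complete because only
provably failed prefixes are discarded. A node is accepting when its data
state satisfies the goal under subsumption and all monitors accept.

Solutions are enumerated from the layered graph after a backward
reachability pass marks the prefixes that can still reach an accepting
node within the bound, so enumeration work is proportional to the number
of solutions times the bound, not to the raw search tree. Expansion order
is fixed — tools alphabetically, then output formats — and the final set is
sorted by (length, tool names, state formats), making output byte-stable
across runs.

Three deliberate semantic choices:

* **Zero-length solutions** are admitted when the initial state already
  satisfies the goal and all constraints hold on the empty trace. None of
  the bundled use cases exercises this; the degenerate case is still
  well-defined and tested.
* **Cycles are allowed** up to the bound unless a constraint forbids them.
  Repeated validation steps, for example, are legitimate (if pointless)
  pipelines and are exactly why the converter no-repeat rules exist.
* **Counting mode.** State-annotated paths are the primary count (the
  merged solution graph counts paths through concrete data-item nodes);
  `uniqueToolSequences()` and the command-line `--count-mode` flag provide
  the collapsed alternative.

`validateSolution()` is an independent checker: it re-derives every
invariant (step compatibility, declared outputs, goal subsumption,
declarative constraint semantics) without touching the monitors or the
search, and is used to cross-validate every synthesized solution in the
tests.

# The bundled proteomics domain

The fixture models 22 tools of the shotgun-proteomics ecosystem over an
EDAM-1.18-style excerpt (40 concepts). Four specifications ship with it;
all start from mass-spectrometry spectra in Thermo RAW format:

1. **Retention-time modelling** — goal: amino acid index (hydropathy);
   require peptide identification, PSM validation and retention-time
   prediction; forbid protein identification.
2. **Enrichment analysis** — goal: pathway or network; require peptide
   identification and gene-set enrichment analysis, in that order, and
   ProteinProphet only after PeptideProphet.
3. **PTM localization** — goal: protein identification report; require PTM
   identification after PSM validation, validation after database search,
   and at most one validation step.
4. **iTRAQ quantification** — goal: gene expression profile; require
   iTRAQ, only after PSM validation.

With the bundled model these yield 31 pipelines at the minimal length 4
(use case 1), 20 at the minimal length 6 (use case 2), 13 at length 4
(use case 3) and 16 at length 4 (use case 4).

## Reconstruction and calibration

The authoritative per-tool format annotations for this tool collection are
not bundled; the fixture is a reconstruction. Port formats were first set
to what each tool actually reads and writes (msconvert fans a RAW file out
into five open spectra formats; Comet consumes all five and emits pepXML;
X! Tandem emits its own XML, converted by Tandem2XML; SearchGUI hands an
archive to PeptideShaker; the TPP validators speak pepXML, and so on), and
the remaining freedom — which of several plausible formats a port
declares — was then calibrated against published solution-space sizes.

The count-sensitive choices, also recorded in the fixture's `notes` field:

* three pepXML/mzIdentML-capable PSM validators (PeptideProphet, iProphet,
  Percolator) besides PeptideShaker — with fewer validators the length-4
  space of use case 1 cannot reach 31 under realistic formats;
* rt4 accepting pepXML, mzIdentML and tabular input, and writing a single
  tabular index; PeptideShaker exporting tabular, CSV and mzIdentML
  reports; idconvert emitting pepXML, mzIdentML and tabular text;
  xml2tsv/SSRCalc handling tabular, CSV and plain-text variants.

Calibration reproduces exactly: 31 at length 4, minimal lengths 4/6/4/4,
20 at length 6, 13 and 16 at length 4. The *cumulative* use-case-1 counts
at depths 5 and 6 computed from this model are 389 and 2606, against
published totals of 388 and 3127. A systematic search over realistic
annotation variants (tens of thousands of candidate format-set
combinations) could not close the depth-6 gap while keeping the seven
structural quantities exact: the published depth-6 mass implies a richer
identification-layer fan-out (more tools and/or more formats per port)
than the available evidence pins down. The package reports what its model
actually computes; the discrepancy is stated rather than fitted away.

# The random-domain generator

Property tests run against seeded random domain models
(`randomDomain()`): a random tree-with-occasional-extra-parent taxonomy
per branch and tools with type-correct random ports. Generation is a pure
function of its configuration; it emulates the *shape* of real domain
models (small DAG taxonomies, sparse tool connectivity) but none of their
semantics — formats are unnamed, operations carry no meaning, and port
assignments are independent. Passing the oracle-equivalence suite on such
models therefore demonstrates the correctness of subsumption, monitors and
search on arbitrary structures, not the fidelity of any particular domain
content; fidelity claims rest on the curated fixture and its listed-
pipeline checks.

Default problem sizes keep independent oracles affordable: the
brute-force enumeration oracle (no pruning, declarative filtering) runs on
200 models with up to 6 tools, 3 formats per branch, 2 formats per port
and bound 4; monitor/declarative equivalence uses 1050 random traces of
length up to 7; subsumption properties use random 12–15-concept DAGs.

# Degenerate inputs and numerical choices

There is no floating-point numerics in the package; determinism questions
reduce to ordering, which is fixed everywhere (C-locale radix sort on
names and curies). Degenerate cases are defined rather than rejected: an
empty tool list is a valid domain model; an empty trace satisfies all
templates but `use`; a specification whose bound is exhausted returns an
empty solution set carrying the searched depth, not an error; mixed-length
solution sets refuse to merge into one graph (per-step-index merging is
only meaningful at a fixed length — global merging could create paths that
correspond to no solution).

# Limitations

* Only is-a subsumption is used; other ontology relations are ignored.
* One input and one output port per tool; multi-port tools are rejected
  explicitly, and non-linear workflows (parallelism, branching, loops)
  are out of scope.
* The five templates do not cover nested temporal operators.
* Synthesized pipelines are abstract: the exported skeletons name tools
  and formats but cannot supply tool parameters, so they are starting
  points for implementation, not executable workflows.
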