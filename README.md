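# edamcompose

Automated composition of mass-spectrometry data-analysis pipelines from
semantically annotated tools.

Proteomics data analysis chains many single-purpose command-line tools —
raw-file converters, peptide database search engines, statistical
validators, quantification and enrichment tools — and working out which
combinations are type- and format-compatible is tedious and error-prone.
`edamcompose` does it mechanically. Tools are annotated with EDAM-style
concepts (an *operation* they perform, plus a *data* and one or more
*format* concepts per input and output port); a workflow specification
gives the initial data state, a goal class, and temporal constraints; the
package then enumerates **every** linear pipeline, up to a length bound,
that transforms the input into the goal while satisfying all constraints.

## The method

A *domain model* is a triple (taxonomy, tool annotations, global
constraints). The taxonomy is an is-a DAG over operation, data, format and
topic concepts; subsumption `c ⊑ d` is reflexive–transitive reachability
over parent links. A tool `t` with input port `(D, {F₁…Fₖ})` is applicable
in a concrete state `(d, f)` iff `d ⊑ D` and `f ⊑ Fᵢ` for some `i`; it
yields one successor state per declared output format.

Constraints are finite-trace temporal properties over the tool sequence,
written in five natural-language templates:

| template | semantics on a trace `t₁…tₙ` |
|---|---|
| `use A` | some `tᵢ` matches A |
| `do not use A` | no `tᵢ` matches A |
| `use A only after B` | every `tᵢ` matching A has an earlier `tⱼ` matching B |
| `do not use A more than once` | at most one `tᵢ` matches A |
| `do not use A directly after A` | no `tᵢ`, `tᵢ₊₁` both match A |

A filler A is either a concrete tool or an operation class, matched against
a tool's annotated operations under subsumption. Each constraint compiles
to a deterministic 2–3-state monitor whose acceptance provably equals the
declarative semantics (this equivalence is property-tested). Synthesis is
breadth-first search over the product of concrete data states and the joint
monitor state; paths entering a reject sink are pruned immediately, which
bounds the frontier by |states| × Π(monitor states) × bound. Solutions are
state-annotated paths: the same tool sequence routed through different
intermediate formats counts separately (a counting mode collapsing to
distinct tool sequences is also provided).

The package ships a calibrated domain model of 22 shotgun-proteomics tools
(msconvert, idconvert, Comet, X! Tandem, Tandem2XML, SearchGUI,
PeptideProphet, iProphet, Percolator, PeptideShaker, PTMProphet,
ProteinProphet, xml2tsv, SSRCalc, rt4, extract_protein_names, GeneTrail2,
EnrichNet, gProfileR, Libra, isobar) with four ready-made specifications:
retention-time modelling, protein identification + enrichment analysis,
PTM localization, and iTRAQ quantification, all starting from mass spectra
in Thermo RAW format.

## Worked example

PTM localization (use case 3): identify and localize post-translational
modifications with a single, validated peptide-spectrum-match step.

```r
library(edamcompose)
model <- proteomicsDomain()
spec  <- useCaseSpec(3, model)
spec@maxLength <- 4L; spec@mode <- "up_to_bound"
spec
#> WorkflowSpec
#>   input:  ( data:0943 , format:3712 )
#>   goal:   ( data:0945 , format:1915 )
#>   bound:   4  mode: up_to_bound
#>   constraints: 4
#>    - use operation:3645
#>    - use operation:3645 only after operation:3648
#>    - use operation:3648 only after operation:3646
#>    - do not use operation:3648 more than once

set <- synthesize(model, spec)
set
#> SolutionSet: 13 solution(s)
#>   per length: 4: 13
#>   product nodes explored: 54
head(solutionsToTable(set), 2)
#>   length                                              tools
#> 1      4 msconvert -> Comet -> PeptideProphet -> PTMProphet
#> 2      4 msconvert -> Comet -> PeptideProphet -> PTMProphet
#>                                                                   formats
#> 1 format:3712 -> format:3244 -> format:3655 -> format:3655 -> format:3655
#> 2 format:3712 -> format:3651 -> format:3655 -> format:3655 -> format:3655
```

Thirteen pipelines satisfy the specification at the minimal length 4: ten
route the spectra through one of five open formats into Comet and the
PeptideProphet/PTMProphet pair, three go through SearchGUI and
PeptideShaker. The merged solution graph (every input-to-output path is a
valid workflow, and the dynamic-programming path count equals the number
of solutions) exports to DOT:

```r
g <- buildSolutionGraph(set, merge = TRUE, taxonomy = model@taxonomy)
g
#> SolutionGraph: 14 nodes, 18 edges, length 4
cat(toDot(g))          # deterministic DOT source
exportSkeleton(solutions(set)[[1]], model@taxonomy)  # shell-script skeleton
```

A candidate pipeline can be checked against a specification with named
verdicts:

```r
workflowFromTools(model, spec,
  c("msconvert", "Comet", "PeptideProphet", "PeptideProphet", "PTMProphet"))$violations
#> [1] "constraint violated: do not use operation:3648 more than once"
```

A thin command-line wrapper (`inst/scripts/edamcompose`) exposes the same
operations as `compose`, `min-length`, `validate`, `graph` and `fixtures`
subcommands.

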