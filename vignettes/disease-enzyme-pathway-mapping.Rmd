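---
title: "Mapping disease-associated enzymes onto a pathway hierarchy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mapping disease-associated enzymes onto a pathway hierarchy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(enzymap)
```

## The problem

A large share of human genetic diseases is caused by variants in enzymes.
Knowing *which biological processes* a disease can perturb requires three
integrations that are individually routine but collectively error-prone:

1. merging disease–gene associations from heterogeneous resources
   (UniProt-, Monarch- and ClinVar-style tables that disagree on gene and
   disease identifiers and carry somatic records that must be excluded);
2. deciding which genes are enzymes (an EC number, or a Gene Ontology
   molecular-function annotation descending from *catalytic activity*,
   GO:0003824);
3. projecting each enzyme's pathway annotations up a Reactome-style event
   hierarchy, from leaf pathways to the top-level roots that name broad
   biology (Metabolism, Signal transduction, ...).

Once those are in place, two classifications fall out. Enzymes split by
association degree into **biunivocal** (one enzyme ↔ one disease),
**univocal** (one disease that also has other enzymes) and **non-univocal**
(≥ 2 diseases). Diseases split by gene count into **monogenic** (one enzyme)
versus **polygenic**, and by pathway footprint into **type A** (all annotated
enzymes confined to a single leaf pathway) versus **type B** (≥ 2 leaf
pathways); diseases whose enzymes carry no pathway annotation at all are
**excluded**. Finally, diseases that reach `n ≥ 2` hierarchy roots connect
those roots pairwise: each such disease adds one count to each of its
`n(n−1)/2` unordered root pairs, giving a weighted co-occurrence network over
roots whose node weight is the number of mapped diseases.

`enzymap` implements the full pipeline, a constructive synthetic-data
generator with a planted truth manifest, and byte-deterministic exports.

## Pipeline model and assumptions

**Ontology descendancy.** Ontologies are parsed from OBO 1.2 text, honouring
only `id`, `name`, `namespace`, `is_a`, `xref`, `is_obsolete`,
`replaced_by`. Descendancy uses *is_a* edges only; `part_of` and other
relations are ignored. This is the minimal reading of "descendant of
catalytic activity": most molecular-function reasoning in practice is pure
*is_a*, and adding `part_of` would silently widen the enzyme set. The
catalytic term set is **self-inclusive** — a protein annotated with
GO:0003824 itself is an enzyme; `descendants()` itself excludes the root, and
callers union it back in where the self-inclusive reading is wanted.
Obsolete terms keep no parents (they never contribute to closures); those
with `replaced_by` forward transparently to their replacement during disease
resolution.

**Disease resolution.** Raw disease keys resolve in a fixed order: canonical
id (after `replaced_by` forwarding) → exact OMIM/Orphanet cross-reference →
exact case-insensitive name. A key matching two canonical diseases is an
ambiguity error naming both, never a guess. Unresolved keys survive only in
the rejects report; all headline statistics use canonically resolved records.
An Orphanet cross-reference is the operational definition of a *rare*
disease.

**Union merge.** Gene keys resolve with the precedence accession → primary
symbol → synonym (symbol/synonym matching is case-folded); a key hitting two
accessions is rejected with reason `ambiguous_gene`. The published merge of
these resources was partly manual and therefore irreproducible; this package
substitutes a deterministic, logged policy and quarantines everything it
cannot resolve, so input records are always fully accounted for:
contributing records + rejects = input. The union is computed at
(accession, canonical disease) granularity; variant-level detail is out of
scope. Merging is order-independent by construction (set semantics plus
sorted output).

**Pathway hierarchy.** The hierarchy is a DAG, not a tree — events may have
several parents — so ancestor expansion is a set union with no double
counting. Node kinds partition events: no parents → root, parents but no
children → leaf, both → internal. A fully isolated node classifies as
*root*; the choice is arbitrary but fixed and tested, and keeps the
three-way partition exact. Two roots (by default those named `"Disease"` and
`"Drug ADME"`) are excluded from all root-level statistics: they stay in the
structure, but `expand_to_roots()` and `roots_of()` drop them and everything
reachable *only* through them. An event under both an excluded and a kept
root keeps its kept roots.

**Disease categories.** The type A/B split is decided at **leaf-pathway
granularity on the union over the disease's annotated enzymes**: a disease
is type A iff that union has cardinality 1 (for polygenic diseases this
means all annotated enzymes share the single pathway). A disease is
*excluded* only when none of its enzymes carries any pathway annotation; a
disease mixing annotated and unannotated enzymes is categorized on the
annotated ones, because partial annotation must not discard a disease. Note
that category assignment intentionally counts leaf pathways regardless of
root exclusion (a disease annotated only under the "Disease" root is still
type A/B) while the *root map* omits it — the two questions are different.
Enzyme-level association-type labels partition enzymes; disease-level
tallies derived from them may overlap (the same disease can appear under
several types), so the summary tables sum only the enzyme and association
columns into their totals row and recompute every overlapping column
(distinct diseases, pathways, roots) from the full sets.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `excluded_root_names` | `c("Disease", "Drug ADME")` | roots dropped from root-level statistics; the conventional exclusion for this analysis, since both collect cross-cutting annotations rather than one biology |
| `species` | `"Homo sapiens"` | species filter applied to the pathway list and annotation files |
| `catalytic_root` | `"GO:0003824"` | the molecular-function term whose self-inclusive descendant set defines "enzyme" together with EC numbers |
| `columns` (per source) | — | column map per source dialect: gene key, disease key, somatic flag column and its truthy values |

Partial EC strings (`"3.-.-.-"`) contribute their level-1 class, which is all
the classification uses; EC class 7 is documented as *Translocases*. Enzymes
with two or more level-1 classes are `Multiclass`; enzymes qualifying only
through catalytic GO terms are `WithoutEC`.

## The synthetic-data generator

`generate_dataset()` plants structure constructively — membership first,
files second — so the manifest is exact rather than statistical. Defaults
describe a scaled-down but structurally faithful study: 29 roots of which 2
are excluded by name, a depth-2 hierarchy with branching 3 (261 leaves), 92
diseases planted as 30/40/3/10/9 across
monogenic-A/monogenic-B/polygenic-A/polygenic-B/excluded (type B outnumbers
type A among monogenic diseases and polygenic A is a small minority, as in
the real landscape), EC class weights proportional to the observed class
sizes of disease-associated enzymes, 75% of diseases flagged rare via an
Orphanet xref, 10% somatic noise rows and 25% cross-source duplication. The
three source files deliberately use different key conventions (accession +
OMIM id; symbol + canonical id; synonym + upper-cased disease name) so a
round trip exercises every resolution path.

What the generator does **not** emulate: realistic pathway sizes and
prevalence distributions, multi-parent pathway events (its subtrees are
trees, so the generator's own leaf→root bookkeeping stays independent of the
traversal code it is used to test; DAG behaviour is covered by hand-built
fixtures instead), variant-level annotation, and non-germline inheritance
structure beyond a binary somatic flag. Passing the planted-recovery suite
therefore shows the *logic* is exact on structurally faithful inputs; it
does not certify counts on any particular database snapshot, which shift
with every release.

`mini_paper_world()` is a fixed, hand-verified miniature containing the
canonical motifs: a pleiotropic kinase annotated to 8 leaves under 6 roots
with two diseases; three proteasome-like subunits sharing 12 leaves under 12
roots; two glycine-degradation enzymes sharing one leaf across three
diseases (polygenic type A); a GO-only enzyme; a multiclass enzyme annotated
only under the excluded "Disease" root; two unannotated enzymes carrying
excluded diseases; a non-enzyme gene; one somatic row and one cross-source
duplicate. Its manifest (10 enzymes, 12 diseases, categories 2/5/3/0/2,
types 5/1/4, 66 network edges) was computed by hand.

## Numerical and ordering choices

* All exports are deterministically ordered (lexicographic ids, sorted
  sources), so repeated runs are byte-identical — verified by hashing every
  output of a double run.
* The per-root univocality percentage is `100 × single/all` rounded to one
  decimal; roots with zero mapped diseases are omitted rather than divided
  by zero; rows sort by total diseases descending with lexicographic ties.
* Histograms cover exactly the observed bucket values and always conserve
  entity totals.
* Degenerate inputs are first-class: empty OBO documents, header-only
  tables, empty union sets, and all-somatic sources all yield empty (not
  failing) results, and every stage failure aborts with a stage-named error.
* Cycles in an ontology or hierarchy are hard errors naming a cycle member;
  dangling references are warnings plus a skip.

## Problem sizes used by the checks

The test suite runs closure oracles on 100 random DAGs of up to 50 nodes
(brute-force reachability by boolean matrix powers — an implementation
deliberately disjoint from the igraph traversal used by the package),
ancestor expansion on 20 random forests, pair-count conservation on random
root maps, and exact planted recovery on 20 generator specifications across
seeds, including the default study-scale spec. These sizes keep the whole
suite in seconds while exercising every branch; the generator scales to
larger worlds by raising `n_roots`, `branching` and the planted counts.

## Known limitations

* Only *is_a* descendancy; no `part_of`, no cross-ontology reasoning.
* The merge policy is a deterministic stand-in for an upstream curation
  process that was partly manual; it is stated, logged and tested, but it is
  not a reconstruction of that curation.
* Root-level statistics depend on the chosen excluded roots; excluding
  different roots changes every downstream network quantity.
* Reaction identifiers are opaque and only counted, never interpreted.
* The pipeline is snapshot-agnostic: it reproduces published headline counts
  only in the arithmetic sense (partition sums, percentages, combinatorial
  bounds), since the underlying databases have moved on.
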