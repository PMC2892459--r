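---
title: "Working with mEPN pathway diagrams: model, validation, simulation and expression overlay"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Working with mEPN pathway diagrams}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mepnkit)
```

## The problem mepnkit addresses

Curated pathway diagrams drawn in the modified Edinburgh Pathway Notation
(mEPN) encode a great deal of machine-usable structure — typed nodes
(components, processes, Boolean operators, edge annotations), sub-cellular
compartments, and literature evidence stored as PubMed identifiers on nodes
and edges — but they normally live as yEd GraphML files that only a human
with a graph editor can exploit. `mepnkit` makes such diagrams operable as
data: it parses and writes the GraphML dialect, checks the notation rules,
computes the summary statistics used to describe curated maps (node-class
census, connectivity, diameter), merges independently curated modules,
exports interaction-evidence tables, executes a diagram as a signalling
Petri net, and overlays expression-derived gene sets onto pathway nodes,
including a built-in co-expression clustering stage.

## The domain model

A pathway is a directed graph of typed nodes. Components (proteins, protein
complexes, genes/DNA, RNA, pathogens, drugs, other molecules) carry an HGNC
label — complexes join member symbols with `:`, and parenthesised aliases
such as `NFKB1 (p50)` are decoration. Processes (binding, dissociation,
phosphorylation `P`, ubiquitination `Ub`, cleavage, translocation,
transcription, the sink `Ø`, pathway modules) connect component states.
Boolean operators (`&`, `OR`) express combinatorial requirements or
alternatives among process inputs, and edge-annotation nodes attach
catalysis/inhibition semantics to an interaction.

The identity of a component occurrence is the triple

> (sorted base symbols, sorted modification states, compartment)

computed by `identity_key()`. The central notation rule — one occurrence of
a component state per sub-cellular compartment — is phrased on exactly this
key, so the key deliberately ignores the order in which complex members are
written. One sharp edge is documented rather than hidden: the key carries no
node category, so a gene node and a protein node with the same symbol in the
same compartment would collide under the uniqueness rule. Real maps separate
them by compartment (genes sit in the nucleus); the synthetic generator
avoids the collision by construction.

The class vocabulary is not hard-coded. A flat notation catalog
(`inst/extdata/mepn_catalog.tsv`: category, subtype, yEd shape, fill colour,
optional display glyph) drives class inference when reading, shape/colour
emission when writing, and the validator's vocabulary check, so the subtype
lists can be extended by supplying another file. The shipped catalog covers
every class the notation names in its published figures; the full notation
specification defines more edge-annotation subtypes than are enumerated
here, which is exactly why the catalog is a configuration surface.

## GraphML input and output

`read_pathway()` parses the yEd dialect. Three choices matter:

* **The key registry is discovered, never assumed.** yEd assigns arbitrary
  key ids (`d0`, `d5`, ...) per file; the reader builds the map from the
  file's `<key>` declarations, so foreign files parse as long as they declare
  `description`/`url` attribute keys and a `nodegraphics` yfiles key.
* **Evidence is free text.** PubMed identifiers are harvested from node and
  edge descriptions by pattern (7–8 digit runs, optional `PMID` prefix).
  This is deliberately permissive — that is how evidence is actually stored
  in curated files — and it means a stray 7-digit number in curator notes
  will be read as evidence.
* **Compartments are group nodes.** The primary mechanism for sub-cellular
  location is the enclosing yEd group node; background-colour regions, the
  other visual convention, are not reliably machine-readable.

`write_pathway()` emits shape and fill from the catalog (unless a node
carries an explicit style, as after overlay styling), appends evidence as a
`PMID:` line in the description, and stores modification states in a
dedicated `mepn.states` key. Round-trip identity — `read(write(g))` equals
`g` field by field — is a tested invariant over randomly generated
pathways.

## Validation rules

`validate_pathway()` reports findings; it never throws. Errors flip
`passed`; warnings do not.

| rule | check | severity |
|------|-------|----------|
| V1 | node class in the catalog vocabulary | error |
| V2 | one component key per compartment | error |
| V3 | component/process alternation of edges | warning; error with `strict` |
| V4 | Boolean in-degree ≥ 2, out-degree ≥ 1 | AND: error; OR: warning unless `strict` |
| V5 | sinks absorb (out-degree 0, in-degree ≥ 1) | error |
| V6 | process carries PubMed evidence | warning |

V3 is a warning by default because the published grammar this package can
rely on is the implied bipartite alternation; the full rule set lives in the
notation specification, and failing a curator's real file on rules not
enforced here would be wrong. `--strict` (or `strict = TRUE`) promotes V3
and the OR-degree check for use on files this package wrote itself. The
same-state-two-compartments case is legal by design: translocation is
depicted exactly that way.

## Network statistics

`census()` counts nodes per class and derives three quantities used to
summarise curated maps: *unique proteins* (distinct base symbols pooled over
protein and complex nodes — a protein, its phosphorylated form, and its
occurrences inside complexes count once), *complexes* (distinct complex keys
with compartment disregarded, so the same dimer either side of the nuclear
membrane counts once), and *regulated genes* (gene nodes with a
transcription-process input). `connectivity_stats()` defines degree as
inputs plus outputs; the identity `mean degree = 2E/N` is asserted in the
tests rather than trusted. `pathway_diameter()` is computed on the
undirected view of the largest connected component: the directed graph
necessarily has unreachable pairs (anything downstream of a sink), so only
the undirected reading of "maximum distance from one node to another" is
finite. A brute-force all-pairs BFS oracle cross-checks it on small graphs.

## Merging curated modules

`merge_pathways()` unifies component nodes with equal keys (evidence and
notes unioned) and never unifies process nodes: two curators' "binding"
steps may differ in unstated context, and the right resolution is human
re-examination, not automation. Where the same ordered pair of component
symbol sets is connected through processes of different subtype in different
inputs, both depictions are kept and the pair is listed as a conflict.
Merging a graph with itself is the identity on component keys, and merging
disjoint graphs is associative — both tested properties.

`extract_interactions()` linearises the graph into evidence-table rows: one
record per (process, inputs, output), with AND operators contributing all
their inputs to one record and OR operators one record per alternative,
catalysis/inhibition sources included as modifiers, and deduplication on
(participant symbols, nature, location). Entrez identifiers are taken from
node URLs that link to a gene record.

## Signalling Petri net execution

`compile_spn()` maps components to places and processes to transitions; AND
folds inputs into consume arcs, OR expands the downstream transition into
one copy per alternative, catalysis becomes a read arc, inhibition an
inhibit arc, and sinks become transitions without produce arcs. Arc weights
are 1 — mEPN labels carry no stoichiometry.

The published source names the signalling-Petri-net approach but not its
scheduling semantics, so the simulator uses the simplest seedable,
analysable choice: **block-synchronous** execution. Each time step visits
the transitions in a uniformly shuffled order; each fires at most once,
consuming then producing immediately. This is documented as swappable. Three
consequences are tested: token conservation on nets whose transitions
preserve counts, monotonicity of inhibition, and the analytic expectation
that two transitions contesting one token each win half the time.
Transcription transitions are not token sources by default (gene→protein
translation edges are deliberately absent from the map style this package
targets); mark genes in the initial marking to drive them. Whether a
catalytic step consumes or merely reads its enzyme is encoded per arc kind;
the compiler default for a catalysis annotation is a read arc.

## The co-expression pipeline

`de_filter()` keeps a transcript iff at any non-baseline timepoint the
absolute log2 mean difference reaches `log2(fc_cut)` **and** the
per-transcript test p-value is at most `p_cut`, both inclusive. The built-in
test is Welch's t on log2 values; the interface accepts a precomputed
p-value table instead, which is the intended slot for an empirical-Bayes
moderated fit — re-implementing one is out of scope, and a moderated
statistic materially changes the kept set at small n.

`correlation_graph()` thresholds *signed* Pearson correlation (default
0.9): co-expression clusters are coherent up- or down-profiles, so
anti-correlated transcripts should not connect. An `absolute` switch exists
for users who want modulus matching.

`mcl_cluster()` implements Markov clustering from scratch — it is the one
algorithmic primitive of the pipeline this package owns. Self-loops of
weight 1, column normalisation, then alternating expansion (matrix
self-product) and inflation (entry-wise power, default 2.2, then column
renormalisation) with pruning of entries below 1e-5 and renormalisation,
until the maximum entry change drops below 1e-8 or 100 iterations. Clusters
are the connected components of the converged matrix's non-zero structure;
singletons are allowed. Column-stochasticity after every iteration is
asserted in tests via the `on_iterate` hook, and the implementation is
cross-checked against an independent plain-loop reference iteration on
bridged-clique graphs. The pruning threshold, self-loop weight and tolerance
are standard MCL practice and are exposed as arguments.

`clusters_to_class_sets()` keeps clusters strictly larger than `min_size`
(default 5), names them `cluster1..k` by decreasing size, and labels each
up/down by the sign of its members' mean peak log2 fold change — feeding
directly into `map_class_sets()`, where a member matches a node iff its
case-normalised symbol equals any base identifier of the node's label. That
single rule is what lets mouse symbols (`Ifnb1`) land on human-labelled
nodes (`IFNB1`) and single genes land on the complexes containing them;
no orthology tables are consulted, which is a documented simplification.
A node belongs to at most one class (first-listed wins, collisions logged),
and a matched complex counts as one matched component.

## What the synthetic data emulates — and what it does not

`synth_pathway()` builds diagrams with exact class counts: base proteins,
phosphorylated variants (via phosphorylation processes), binary complexes
(via binding processes, optionally gated by AND/OR operators), transcribed
genes, sinks and catalysis/inhibition annotations, with compartments,
Entrez-linking URLs and PubMed evidence. Its contract — output validates
strictly, census reproduces the spec, bytes identical per seed — is what the
I/O, validator and statistics tests are built on. It does not attempt
realistic topology (no hubs, no feedback loops, no scale-free degree
sequence), so passing tests say nothing about layout or biology, only about
the mechanics of representation.

`synth_expression()` emulates a cytokine-stimulation timecourse in
macrophages: 5 timepoints (0/1/2/4/8 h) × 3 replicates, planted modules
whose members share a pulse-shaped log2 fold-change profile
(`(t/peak) * exp(1 - t/peak)`, zero at baseline, unit height at the peak)
plus module-correlated noise, and pure-noise background transcripts. The
default separation — within-module correlation ρ = 0.95, noise sd 0.1 log2
units — is chosen so that planted within-module correlation clears the 0.9
edge threshold the pipeline uses downstream; with four modules peaking at
different times, between-module correlations fall in the 0.6–0.85 range and
stay below it. Real array data differ in ways the generator does not model:
heavier-tailed noise, correlated background, probe-level redundancy, and
fold changes that do not follow a clean pulse. Recovery results on this
generator (adjusted Rand, overlay recovery) therefore demonstrate pipeline
correctness, not expected performance on real series.

## Numerical and degenerate-input choices

* Cut-offs are inclusive everywhere (≥ fold change, ≤ p, ≥ r); the cluster
  size filter is strict (> min_size), matching the "greater than" phrasing
  of the convention it follows.
* Zero-variance transcripts are excluded from correlation with a warning;
  transcripts with no surviving edge are dropped before clustering.
* In the Welch step, rows constant in both groups get p = 1 when the means
  agree and p = 0 when they differ.
* Empty graphs: census returns zeros; connectivity and diameter refuse
  (undefined) rather than guessing.
* The simulator restores the caller's RNG state; identical seeds give
  bit-identical trajectories.
* MCL attractor overlaps cannot arise under the connected-components
  reading of the converged matrix; the support graph is symmetrised before
  components are taken.

## A worked example

```{r example}
pw <- synth_pathway(pathway_spec(n_protein = 20, n_complex = 6, n_gene = 4,
                                 seed = 42))
validate_pathway(pw, strict = TRUE)$passed
census(pw)

res <- synth_expression(expression_spec(seed = 43), pathway = pw)
kept <- de_filter(res$expr, baseline = 0, fc_cut = 1.5, p_cut = 0.05)
g <- correlation_graph(res$expr, kept, r_cut = 0.9)
part <- mcl_cluster(g, inflation = 2.2)
sets <- clusters_to_class_sets(part, res$expr, baseline = 0, min_size = 5)
ov <- map_class_sets(pw, sets)
ov
```

## Problem sizes used in the tests and acceptance script

The test suite and `scripts/acceptance.R` run on synthetic graphs of roughly
30–200 nodes, 100-pathway round-trip batches, 10,000-run Petri-net
simulations on 5-node nets, and 400-transcript timecourses. These sizes make
every property exact or tightly bounded (binomial error on the fork
expectation is ±0.005 at one sd) while keeping a full run in well under a
minute; all the algorithms are dense-matrix or list-based and scale
comfortably to maps of a few thousand nodes, the size of published
integrated diagrams.

## Known limitations

* The GraphML writer emits one dialect; it does not cover yEd's full visual
  style space, and polyline edge geometry is preserved but never
  interpreted.
* Symbol matching is identity-based; cross-species overlay relies on
  case-insensitive symbol equality, not orthology.
* The edge-grammar check (V3) enforces only the component/process
  alternation, not the full notation rule set.
* The Petri-net semantics is one defensible choice among several; timed,
  stochastic-rate and continuous interpretations are out of scope.
* The "clusters of interest" step of a real overlay analysis is manual
  inspection and has no operational rule; all size-filtered clusters are
  exported.
```
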