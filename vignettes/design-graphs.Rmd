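---
title: "Design graphs: model, views, editing and repository integration"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Design graphs: model, views, editing and repository integration}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(circuitgraph)
```

## The canonical knowledge graph

`circuitgraph` represents one or more genetic designs as a single typed
knowledge graph. Nodes are keyed by absolute URI — the identifier a part
carries in its home repository — and carry one of a closed set of types:
the genetic part roles (`CDS`, `Promoter`, `RBS`, `Terminator`,
`Engineered-Region`), molecular entities (`Protein`, `Complex`,
`SmallMolecule`), explicit `Interaction` nodes, `Synonym` nodes produced
by repository merging, and `Metadata` nodes (used, for instance, for
ontology terms). Edges are directed and predicate-labelled: containment
(`hasPart`), role-qualified participation in interactions
(`hasParticipant`), interaction typing (`interactionType`), the collapsed
regulatory predicates (`represses`, `activates`, `produces`), synonym
links (`synonymOf`), and identity-weighted similarity (`similarTo`).

Keys are normalized before use (fragment and trailing slash dropped),
because serializations of the same resource URI differ in exactly those
details. Interactions are stored verbosely: an `Interaction` node, an
`interactionType` edge to an ontology term node (repression SBO:0000169,
stimulation SBO:0000170, genetic production SBO:0000589), and one
`hasParticipant` edge per participant with a role qualifier (inhibitor /
inhibited, stimulator / stimulated, template / product). The qualifier is
what makes the collapsed view below lossless: without it, a two-input
interaction could not be re-expanded unambiguously.

`validate_graph()` checks the structural invariants — key syntax, type
vocabulary, sequence alphabet per node type, referential closure of
edges, weight ranges, canonical `synonymOf` direction, root typing, and
that containment restricted to root-reachable nodes forms a forest.
Violations are returned as descriptors rather than raised, so callers
(the writer, the editor) can decide how to react. Every public mutator is
expected to preserve an empty violation list, and the test suite holds
all of them to that contract.

Sequences live in node properties rather than as separate graph nodes;
at the SBOL layer they are expanded into proper `Sequence` objects. This
keeps the in-memory graph small and the projections free of
bookkeeping nodes.

## Reading and writing designs

SBOL3 is the canonical serialization, written as RDF/XML and read in
either RDF/XML or the same dialect produced by other tools; SBOL2 is
read-only and converted to the same internal model on ingest, so one
output dialect keeps the round-trip contract testable. Relations the
SBOL data model does not carry (synonym links, weighted similarity, node
type annotations for non-SBOL node kinds) are serialized under a
companion namespace; a `similarTo` weight, which cannot be a plain RDF
triple, becomes a small reified similarity resource. The writer refuses
graphs with invariant violations and emits statements in sorted order,
so output is byte-stable and `read_design(write_sbol(g))` is
graph-isomorphic to `g`.

GenBank flat files are parsed by a purpose-built reader for the
LOCUS / FEATURES / ORIGIN subset (no installed R package exposes the
GenBank feature table). Each record becomes one root `Engineered-Region`
with one part node per mapped feature; the mapping (CDS to `CDS`,
`promoter` to `Promoter`, RBS to `RBS`, `terminator` to `Terminator`,
everything else kept as `Engineered-Region` with a logged warning) is a
documented decision, since no standard prescribes it. Coordinates are
stored 0-based half-open internally — one convention everywhere prevents
off-by-one drift — and complement-strand features keep their
forward-strand slice with an `orientation = "reverse"` property, which
makes the conversion lossless.

## Views

`project()` derives five views. `full` is the graph verbatim.
`hierarchy` keeps genetic part nodes and containment.
`interaction_verbose` shows entities and interaction nodes with their
qualified participation edges. `interaction` collapses each interaction
node into directed edges from every active participant to every passive
one, with the predicate mapped from the interaction type; consequently
the collapsed edge count is exactly the sum of |active| x |passive| over
interaction nodes, which is what the tests enumerate by brute force.
`protein_network` further contracts genetic production: coding sequences
are replaced by their protein products, and a regulatory edge that
points at a promoter or CDS is re-targeted to the protein(s) produced
downstream of that target. Re-targeting is confined to the same root
design — inferring regulation across separately loaded designs would
invent interactions no input states.

Every projected edge records provenance: the shortest path in the
canonical graph (measured on the undirected skeleton) between the two
linked nodes, and its length. Ties between equal-length paths are broken
by the lexicographically smallest predecessor key, which makes
projections, and therefore exports, deterministic down to the byte.
`shortest_path_annotation()` re-verifies every recorded path against an
independent breadth-first computation (igraph), and `network_info()`
reports node, edge and component counts plus the degree histogram, with
components counted on the undirected skeleton so isolated nodes count.

Presets from the interactive tradition ("interaction standard",
"hierarchy") are configuration bundles naming a view and a mode; layout
computation is deliberately out of scope — exports carry no coordinates,
and positioning is left to downstream tools that read GraphML or
node-link JSON.

## Combining designs

`combine()` implements the three load predicates over a collection of
graphs, with element identity being the node key for nodes and the
(subject, predicate, role, object) tuple for edges: union keeps
everything, intersection keeps elements present in every graph, and
difference keeps elements present in exactly one graph — the literal
reading of "only exist within one graph" for more than two inputs. The
result is repaired to referential closure: an edge survives only when
both endpoints do, while nodes are never dropped on account of a dropped
edge, because nodes are elements in their own right. When property maps
conflict in a union, the first-loaded value wins and the conflict is
logged; silent merging would make results depend on inspection order.
The two node modes (`node_mode()`) operate on node sets with induced
edges. All set operations work on canonical graphs, before projection,
so any view can be taken of a combined graph.

## Editing

Edits arrive against a view, not against the canonical graph, so the
editor does three things: validates the node key, filters predicates by
the view's rule table, and expands accepted edits back into canonical
structure. Key validation distinguishes an offline syntactic policy
(URI well-formedness only; remote resolution is a deployment concern)
from corpus lookup, where unknown keys are matched against a part-record
corpus by name (normalized Levenshtein similarity on lowercased names)
and by sequence (alignment identity, exact-match fast path), and
candidates scoring at least 0.8 are offered in deterministic order.
Both the candidate threshold and the rule table are configurable — the
table can be loaded from JSON so deployments can extend the predicate
vocabulary without code changes.

The shipped rule table encodes the one externally fixed constraint —
genetic production requires a coding-sequence subject and a protein
object — plus conservative typings for repression, activation and
containment. Beyond production, the per-view predicate vocabulary is not
externally specified; the shipped table is this package's documented
extension. Interaction-view edits expand into a freshly minted
`Interaction` node (keys `<namespace>/interaction_<n>` with a
deterministic counter, so repeated runs produce identical files), an
`interactionType` triple and two qualified participations; hierarchy
edits add containment directly after a cycle check; full-view edits add
the raw triple. Expansion applies the candidate triples, re-validates
the whole graph, and rolls back on any violation — rejection, not
corruption, is the failure mode. Deletion and renaming are out of
scope; the editor adds.

## Repository integration

`build_dataset()` filters raw part records: duplicates first (later
records with an identical sequence-and-role pair within the same
source), then records without descriptions, each removal explained.
`merge_datasets()` then merges any number of datasets into one network.
Records with identical sequence and role — within or across datasets —
are synonyms: the first-loaded record contributes the part node and
each further key becomes a `Synonym` node linked by `synonymOf`, so the
network carries no duplicate parts but no identifier is lost. Requiring
role agreement (rather than sequence equality alone) is a choice: the
same physical sequence annotated as promoter in one source and as
terminator in another is a data conflict, not a synonym. Surviving
same-role pairs with alignment identity in [threshold, 1) get a
`similarTo` edge weighted by identity — derivative candidates. The
default threshold of 0.95 is configurable; identity is computed as
matches over alignment length under global alignment with match +1,
mismatch -1, gap -1 (`pairwise_identity()`, backed by Biostrings).
Records without sequences participate by key only: there is no basis
for calling them similar.

All-pairs alignment is quadratic, so candidate pairs are prescreened by
a length-ratio floor of 0.8 and a k-mer (k = 8) Jaccard floor. The
Jaccard floor is set at 0.3: a pair at the 0.95 identity floor can lose
up to eight 8-mers per substitution, so its Jaccard can fall to roughly
(0.6L - 7)/(1.4L - 7), about 0.38-0.43 for realistic part lengths — a
floor of 0.5 would discard true derivative pairs, while 0.3 sits safely
below the bound and provably changes no answers at the default
threshold (the test suite compares prescreened and exhaustive runs).

## The fixture generators

`make_design()` and `make_part_corpus()` generate every input the tests
use; nothing is downloaded. Designs come in known shapes — a NOT gate
(one transcription unit whose protein represses its own promoter), a
repressilator (three units in a repression 3-cycle), nested containment
trees, and GenBank flat files — each with a manifest of expected counts
per view, so tests compare projections against construction truth.
Corpora plant structure whose ground truth is recorded exactly: a
fraction of records duplicated under new keys (synonyms) and a fraction
duplicated with isolated point substitutions (derivatives). Substitutions
avoid the first and last five bases and are kept at least eight bases
apart; isolated substitutions leave the ungapped diagonal as the unique
optimal global alignment, so the manifest identity 1 - k/L is exactly
the alignment identity the merger must report. Generators save and
restore the session RNG state, and identical spec plus seed yields
byte-identical output.

The generators emulate structure, not biology: sequences are uniform
random DNA without codon structure, GC bias or repeats, parts do not
share homologous motifs, and mutation is substitution-only. Passing
tests therefore demonstrate the graph semantics — conversion, collapse,
algebra, recovery of planted relations — not robustness to the
ambiguity of real repository data, where near-duplicates involve
indels, rearrangements and inconsistent annotation.

## Problem sizes and defaults

The shipped checks run at desk scale, chosen to exercise every code
path several times over: 50 seeded designs for round trips, 200 random
graph pairs for the set algebra, 100 random graphs for component
counting, and merge corpora of 50 records with 10% planted duplicates
and 10% mutated copies at 3% per-base substitution. Defaults:
derivative threshold 0.95, candidate threshold 0.8, k-mer prescreen
k = 8 at Jaccard 0.3, minted-key namespace
`https://circuitgraph.local/edit`; all live in `cg_config()` and can be
overridden by a flat YAML config file or per-call arguments.

## Known limitations

Only a pragmatic subset of SBOL is handled: components, containment
features, sequences, interactions and participations — not constraints,
locations on sequences beyond start and end, provenance or attachments.
SBOL2 is read-only. The GenBank reader handles single-range and
complement locations but not `join()` spans. The containment-forest
invariant rejects designs that reuse one part instance under two
parents (SBOL would model reuse through distinct subcomponent
instances, which is how converted designs express it). Derivative
detection is pairwise only — no clustering, no alignment-guided
grouping — and the merger never infers interactions absent from its
inputs.
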