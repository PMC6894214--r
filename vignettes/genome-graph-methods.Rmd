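---
title: "Building and querying genome graphs with pangraphr"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building and querying genome graphs with pangraphr}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The model

A single linear reference sequence misrepresents a collection of related
genomes: genes missing from the reference vanish from every downstream
analysis, and rearrangements scramble the interpretation of coordinates.
`pangraphr` represents a set of isolate genomes as a **directed sequence
graph**. Each node holds a sub-sequence that is homologous between the
isolates listed in its `ids` attribute, and each genome is a labelled
walk: concatenating node sequences along an isolate's walk — reverse
complementing the nodes it traverses in inverted orientation —
reproduces that genome byte for byte. This *round-trip identity* is the
master invariant of the package; every build verifies it before
returning, and the test suite asserts it on all fixtures.

Homology here means shared evolutionary origin as established by
alignment, not mere sequence identity. Consequently the structure
favours biological interpretability over maximal compression: tandem
repeats present in only one isolate become an ordinary insertion node
(never a self-loop — the graph contains none), so that every node can
carry explicit start and stop positions for each of its isolates.

### Coordinates and inversions

Nodes store, for every member isolate, the 1-based inclusive
forward-strand interval the node's sequence occupies in that genome, as
a `(leftend, rightend)` pair. A segment that an isolate carries in
inverted orientation occupies forward-strand positions `[s, e]` but is
stored with `leftend = -e, rightend = -s`: the values are both negated
and *reversed*, making `|leftend| >= |rightend|` a machine-checkable
inversion flag, and reconstruction reverse-complements the node
sequence. The published attribute scheme for such graphs states only
that inverted occurrences carry "reversed negative" values; the exact
ordering used here is this package's documented convention, chosen for
that checkability, and is not a claim about any other implementation.

Because each node records one coordinate pair per isolate, an isolate
can traverse a node at most once; segmental duplications within one
genome therefore become distinct nodes. Node sequences are stored in
the orientation of the first member isolate (in graph isolate order),
which consequently always has positive coordinates. `N` and IUPAC
ambiguity letters are literal characters: they group only with
identical characters during collapse, so no identity is ever inferred.

## Construction

Construction is two-staged, mirroring how whole-genome aligners
operate:

1. **Structural graph.** The genomes are decomposed into co-linear
   blocks — either parsed from an XMFA file produced by a whole-genome
   aligner (progressiveMauve dialect: `> seqnum:start-end strand`
   headers, `=` separators, sequence indices mapped to isolates by
   input order), or, in *co-linear mode*, a single whole-genome block
   for rearrangement-free inputs. Each block becomes one temporary
   node named `Aln_<k>`; edges join blocks adjacent in each isolate's
   genome. Regions covered by no block are synthesised into
   single-isolate blocks so that every genome remains fully tiled —
   round-trip correctness takes precedence over aligner coverage.
   Blocks are normalised so the first graph isolate present is on the
   `+` strand; a whole-block inversion is thus a single node with
   negative reversed coordinates for the inverted isolate, and the
   breakpoints live in the flanking edges.

2. **Realignment and collapse.** Every block containing more than one
   isolate is realigned with the selected MSA tool and collapsed:
   alignment columns are partitioned by identical characters (gap rows
   absent), maximal runs of columns with the same partition each emit
   one node per group, and nodes are named `<block>_<n>` sequentially
   in column order (within a column, the group containing the
   alphabetically smallest isolate first). Per-isolate coordinates are
   derived from a per-row cursor plus the row's genomic offset; `-`
   strand rows receive negative reversed values. The collapsed
   subgraph then replaces its temporary node, with incoming and
   outgoing edges rewired per isolate to that isolate's first and last
   sub-node. Single-isolate blocks pass through unchanged: there is
   nothing to align.

### Alignment machinery and its parameters

External aligners (`mafft`, `muscle`, `clustalo`) are wrapped behind a
uniform interface; a missing executable raises a distinct
`aligner unavailable` condition rather than failing silently. The
package also ships a built-in aligner so graphs can be built and the
whole pipeline tested without external binaries: global pairwise
alignment with affine gaps (delegated to `Biostrings`'s C
implementation behind the package's scoring interface), extended to a
deterministic progressive MSA that aligns each sequence in input order
against the running profile's majority-character consensus (ties to the
alphabetically smallest character).

Default scoring: match `+1`, mismatch `-1`, gap open `-2`, gap extend
`-0.5`, where a gap run of length $L$ scores
$\mathrm{open} + (L-1)\,\mathrm{extend}$. The penalties favour one
contiguous gap over scattered gaps, which matches the block-wise indel
structure the collapse step expects (a `k`-base insertion should become
one private node, not several). The built-in progressive strategy is
adequate for the highly similar sequences found *within* co-linear
blocks; divergent inputs should go through an external MSA tool, which
is the intended production path. The test suite pins the pairwise
scores to two independent oracles: exhaustive enumeration over all gap
placements (tiny lengths) and a separately written affine-gap dynamic
program (lengths up to 8, 200 seeded pairs).

## Queries

All downstream operations use the coordinate system rather than
re-alignment:

- `extract_subsequence()` slices the nodes overlapping an interval
  (reverse-complementing inverted occurrences) without reconstructing
  the genome; it is tested for equality against full-reconstruction
  slicing, inversion-spanning intervals included.
- `translate_position()` maps a position through its node to another
  isolate at the same within-node offset; at an inverted occurrence the
  offset is reversed so the *biologically homologous base* is returned.
  Positions inside nodes private to other isolates return `NA` —
  coordinates are never interpolated. Results are negative when the
  target occurrence is inverted; the absolute value is the
  forward-strand position.
- `largest_conserved_node()` returns the longest node shared by every
  isolate (ties by name); `isolate_specific_nodes()` returns
  single-isolate nodes strictly shorter than a bound (default 3 bp),
  i.e. candidate private SNPs.
- `extract_gene_subgraph()` returns the nodes covering a feature. The
  covered set is anchored on the feature's isolate and then extended,
  per other isolate, with the nodes falling inside the genomic span the
  shared nodes delimit there; without this extension the parallel
  variant nodes of the *other* isolates — the interesting part of a
  gene comparison — would be invisible. Every returned node carries a
  `seq_len` attribute for visualisation (e.g. mapping node width to
  length in Cytoscape after GraphML export).
- `homology_matrix()` matches genes between isolates by *position in
  the graph*, not sequence similarity: a gene's footprint is the set of
  (node, within-node interval) pairs it covers; two genes match when
  their footprints share at least `overlap_threshold` (default 0.5) of
  the shorter gene, assigned one-to-one greedily by descending shared
  length (ties by gene id). The published description of this analysis
  gives no quantitative matching rule; the footprint-overlap criterion
  and tie-breaks are this package's documented choices. The 0.5 default
  tolerates boundary indels while rejecting unrelated loci, and the
  positional definition is what lets high-identity paralogues at
  distinct loci map to their positional counterparts rather than to
  each other.

## Serialization and reporting

GraphML is the primary exchange format, written with the flattened
attribute scheme generic viewers expect: node keys `name`, `sequence`,
`ids` (comma-separated), and one `<isolate>_leftend` /
`<isolate>_rightend` long-integer pair per member isolate; edge keys
`name` (`"<source> (-) <target>"`) and `ids`. Import reverses export
exactly and fails with the offending node named when a coordinate key
is missing. A native serialized object (RDS) is supported alongside,
and `generate_report()` summarises a graph: node and edge counts,
average in/out degree (`edges / nodes`), total node sequence length,
and density, computed with the directed simple-graph formula
$m / (n(n-1))$ (the published report names "density" without a
formula).

## The synthetic-genome generator

Tests need genomes whose true relationship is *known*, so the package
generates them: a random root is mutated independently per derived
genome with per-base substitutions, geometric-length indels (mean 3 bp
— short indels dominate within co-linear blocks), tandem-repeat
expansions, and segmental inversions, all drawn non-overlapping and
recorded as an event list plus a piecewise root-to-derived coordinate
map. Replaying the events reproduces the derived genome exactly, which
makes the truth usable as an oracle for reconstruction, position
translation, conserved-region and homology tests. By default the first
genome in a fixture set is the unmutated root, so root coordinates
double as isolate-1 coordinates.

When rearrangements are present the generator also emits a correct
XMFA decomposition derived from the truth, with co-linear blocks cut
on a ~1 kb grid (adjusted so each inversion is exactly one block).
The 1 kb granularity is typical of locally co-linear blocks emitted by
whole-genome aligners at these divergences and keeps each block's
O(nm) realignment small. Rows in the emitted XMFA are right-padded to
a common width rather than pre-aligned — their interval and strand
metadata is exact, and the builder realigns every multi-isolate block
anyway.

Independent mutation of every genome from the root is deliberately an
upper-bound regime for graph growth: in real clades mutations are
shared along the phylogeny, so fewer new nodes per added genome are
needed. The generator does not emulate phylogenetically correlated
variation, sequencing error, or assembly artefacts; passing tests
therefore demonstrate correctness of the graph semantics, not
robustness to misassembly.

## Problem sizes, numerics, degenerate inputs

The shipped tests build graphs from up to 10 genomes of 10 kb (1 kb
blocks) and verify byte-identical reconstruction for all of them;
graph-growth behaviour is characterised on 1 kb sequences at one
substitution per kb, where node count grows at most linearly with the
number of genomes (bounded by three nodes per substitution carried by
the newly added genome) and stays at a single node for identical
copies. These sizes were chosen to exercise every code path —
inversions, coverage gaps, strand flips, multi-block splicing — while
keeping the default test run fast; the construction itself has no
hard-coded size limits, and scaling is governed by the O(nm) cost of
per-block MSA.

Degenerate inputs are defined rather than accidental: empty sequences
are rejected everywhere except pairwise alignment (where one empty
side yields an all-gap row at the documented gap cost); zero mutation
rates reproduce the root exactly; a graph with a single node has
density 0 by convention; DP traceback ties inside the built-in aligner
resolve deterministically through `Biostrings`; all other tie-breaks
(group order within a collapse column, conserved-node ties, homology
candidates) resolve alphabetically. Mutation rates that cannot be
placed without overlap on a short root raise an error instead of
silently dropping events.

## Known limitations

- Co-linear block discovery is delegated: without an XMFA file the
  builder assumes rearrangement-free genomes. Translocation detection
  itself is out of scope.
- The built-in progressive aligner is profile-greedy and
  order-dependent; it is not a substitute for mafft/muscle/clustalo on
  divergent blocks.
- Each isolate traverses a node at most once, so within-genome repeat
  family structure is represented by distinct nodes, trading
  compression for coordinate explicitness.
- Gene homology is purely positional; genes relocated by large
  rearrangements between annotated loci will not be matched by
  footprint overlap.
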