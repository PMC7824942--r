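---
title: "TCR similarity, sharing networks and CDR3 motifs: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TCR similarity, sharing networks and CDR3 motifs: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcrsimnet)
```

## The problem

T cells recognise antigen through the hypervariable CDR3 loops of their
receptor's α and β chains. When an antigen drives a response, it expands
clones, and different subjects responding to the same antigen often carry
*similar* — not identical — CDR3 sequences. In low-volume compartments
such as cerebrospinal fluid, where a sample yields on the order of a
thousand T cells, detecting convergent receptor sequences across samples
and diagnosis groups is one of the few ways to get at shared antigen
specificity without knowing the antigen. `tcrsimnet` implements that
detection chain: filter to trustworthy receptors, score all pairs with a
normalised edit-distance similarity, cluster above a threshold, organise
sharing by sample and diagnosis group, and enumerate CDR3β motifs for
database lookup.

## The filter chain

Raw per-cell contig tables (10x Cell Ranger VDJ dialect or AIRR
Rearrangement) are parsed losslessly: every row becomes a record, with
non-TCR loci kept as `chain = "other"` and CDR3s outside the strict
20-letter uppercase amino-acid alphabet (including Cell Ranger's `"None"`)
flagged unusable rather than dropped. Filters then act visibly, each
reporting its in/out counts:

1. **Assembly** groups contigs by `(sample, barcode)`; only productive,
   usable, high-confidence TRA/TRB contigs populate a cell's chain sets.
   Whether non-high-confidence contigs should enter at all is not settled
   practice; we exclude them by default (they are Cell Ranger's own "do
   not trust" flag) with `require_high_confidence = FALSE` to retain.
2. **Unambiguity.** Paired mode keeps cells with exactly one productive α
   and exactly one productive β; a cell with two βs cannot be assigned a
   single receptor and is removed, not repaired. β-only mode (for
   external datasets without α information) requires exactly one β.
3. **Clonotype calling** groups cells with identical CDR3 amino-acid
   sequences — `(cdr3a, cdr3b)` in paired mode — and, by default, within a
   sample. A clone is one subject's expansion: the same sequence in two
   subjects is a *sharing* finding, not one clone, so cross-sample
   identity is surfaced by the similarity network (identical sequences
   score exactly 1.0 and always connect) rather than merged at calling
   time. `scope = "global"` pools across samples when that is wanted.
   Identity is at the amino-acid level because convergent receptors with
   different nucleotide rearrangements are precisely the signal of
   interest.
4. **Clonal expansion**: clonotypes with `size >= 2` (a sequence seen in
   at least two cells) proceed to similarity analysis. Singletons remain
   in the clonotype table and in clone-size bins (default `1`, `2–5`,
   `>5`; only the `>5` boundary has an established reference point, the
   bins are configurable).

## L-sim

For strings $a,b$ with unit-cost edit distance $d$:

$$\mathrm{Lsim}(a,b) = 1 - \frac{d(a,b)}{\max(|a|,|b|)} \in [0,1]$$

The edit distance is computed exactly (integer dynamic programming in
C++), and the score is a ratio of integers, so a threshold comparison like
`> 0.8` has no floating-point ambiguity: a pair at exactly 0.8 does not
connect. Properties relied on and tested: symmetry, $\mathrm{Lsim}=1$ iff
the strings are equal, the triangle inequality for $d$, and agreement with
an independent naive full-table implementation.

How to score a *paired* receptor with a single-string similarity is a
genuine design choice. The default concatenates α and β without a
separator and scores once — the closest single-string reading of scoring
"TCRαβ sequences", and the one used by the reference workflow this package
generalises. Two alternatives are first-class: `per_chain_mean` (mean of
α–α and β–β scores; differs when chain lengths are very unequal, since
concatenation weights chains by length) and `beta_only`. The pairing mode
is recorded on the similarity object.

**Clusters** are connected components of the `L-sim > τ` graph with at
least two members, ordered by size then smallest member id. Components —
not community detection — because the object of interest is "is there any
chain of high-similarity links", and because components make the
τ-refinement property exact: raising τ only ever splits clusters, so a
τ = 0.9 network is an edge-subgraph of the τ = 0.8 network.

τ defaults to 0.8: on unrelated repertoires the background L-sim
distribution is unimodal around ~0.2–0.5 (it is driven by length
differences and chance matches) with well under 1% of pairs above 0.8, so
0.8 sits in the far tail of the null while still admitting 1–2
substitutions between 13–26-residue sequences.

## Networks and group sharing

The network has one hub per sample and one leaf per clonal clonotype,
attached to its hub; leaf–leaf edges carry the L-sim score. Isolated
leaves are retained deliberately — the picture should show each sample's
clonal repertoire, not only its connected part. The group-sharing matrix
counts similarity edges by unordered diagnosis-group pair. Edges between
two clonotypes of the *same* sample are excluded by default (the quantity
of interest is sharing between unique samples; `include_within_sample =
TRUE` restores them). We count *edges*, not distinct TCRs: a clonotype
similar to three others contributes three units of sharing. That is an
interpretation — counting distinct TCRs per group pair is equally
defensible — and it is stated here because the two disagree on dense
clusters.

Exports are GraphML or node/edge CSVs; both round-trip. Plotting is a
best-effort force-directed helper; all tested guarantees are on the graph
structure.

## Motifs

CDR3β motifs are every contiguous substring of length ≥ `min_length`
(default 3) of each clonal clonotype's CDR3β after removing `trim = 2`
residues from each end, where the sequence is germline-conserved and
uninformative about specificity. Frequency counts **distinct clonotypes**
containing the motif, once each: counting cells would let one large clone
masquerade as a shared motif, and counting occurrences would double-count
repeats within one sequence. Length-1/2 motifs are enumerable
(`min_length = 1`) but excluded by default as uninformative. Frequencies
are anti-monotone under motif extension, which the tests exercise as a
property.

Database lookup is substring containment of the motif in the full,
*untrimmed* CDR3β of a McPAS-TCR-layout table (the database stores
complete junctions; trimming is a repertoire-side noise-reduction step),
after uppercasing both sides. Hits are tabulated by pathology and T cell
type at the entry level — duplicate database rows count twice, since
curation-level deduplication is the database's concern, not ours.

## The synthetic generator

`sim_config()` describes a stated world and `generate_repertoire()` emits
it deterministically under a seed:

- **Cohort**: 8 HC / 4 AD / 5 MCI / 7 PD samples of 1300 cells each by
  default — the scale of a realistic multi-sample CSF study. Tests and
  examples use smaller cohorts (e.g. 8 × 120 cells) purely for runtime;
  that scaling is stated where it happens.
- **Background**: CDR3s are uniform-random interiors of length 10–18
  between fixed C/F termini; clone sizes are `floor + geometric(p = 0.45)`.
- **Planted clusters**: a random seed αβ pair per cluster (α 14, β 12
  residues); each member is one interior substitution away from the seed,
  so any two members differ by ≤ 2 edits over 26 residues
  (L-sim ≥ 24/26 ≈ 0.923 > 0.8). Defaults: three clusters of 4, 5, 6
  members, clone size 2, hosted in AD/MCI samples.
- **Planted motif**: one 9-mer inserted in the trimmed interior of the
  CDR3β of 5 distinct clonal carriers. Cluster seeds use 12-residue βs so
  their trimmed interiors (8 residues) cannot produce competing length-9
  motifs.
- **Separability**: background (and carrier) sequences are
  rejection-sampled to keep their L-sim to every cluster seed below
  `tau − margin` (0.8 − 0.1), and cluster seeds are kept below 0.6 of
  each other. Since one substitution moves an L-sim by at most 1/26,
  no background sequence can reach 0.8 of any planted member: cluster
  recovery on this world is separable by construction, which is exactly
  what makes it a *validation* of the implementation rather than of the
  biology.
- **Noise**: 5% of background cells gain a second productive β
  (ambiguous; removed by the filter chain) and 5% an extra non-productive
  contig (removed at assembly). Planted cells are kept clean so ground
  truth is exact.

What the generator does **not** emulate: V(D)J recombination statistics,
gene-segment usage, biased amino-acid composition, sequencing error, or
real clone-size tails. A green recovery test therefore establishes that
the pipeline finds structure of the planted geometry when separation
holds — it says nothing about sensitivity on real repertoires, where
convergent TCRs are not guaranteed a 0.1 margin from the background.

`score_recovery()` reports, per planted cluster, the recall of the
best-matching detected cluster and its contamination (members not planted
in that cluster), and per planted motif its rank and frequency at its
length.

## Numerical and degenerate-input choices

- Distances and scores derive from integers; no tolerances anywhere in
  the decision path. Cluster and report orderings break ties
  lexicographically so outputs are byte-reproducible.
- `lsim("", x)` is 0 for non-empty `x`; `lsim("", "")` is an error
  (undefined, and a symptom of unvalidated input).
- A clonotype whose trimmed CDR3β is shorter than `min_length`
  contributes no motifs and is counted in a log message.
- Clonotype ids are assigned after sorting by key, so calling is
  invariant to input row order.
- Empty inputs: header-only contig files parse to empty tables with a
  warning; an all-singleton repertoire warns at the clonal filter; a
  similarity stage with fewer than two clonal clonotypes aborts the
  pipeline with the stage name.

## Known limitations

- L-sim is a pure string metric: it has no substitution-matrix weighting
  (BLOSUM), no position weighting, and no V/J-gene awareness. TCRdist- or
  GLIPH-style metrics are out of scope.
- The α/β concatenation default weights chains by their length; use
  `per_chain_mean` when that is a concern.
- Motif lookup is exact substring containment — no fuzzy database
  matching.
- Group-sharing counts are edge counts (see above).
- The CLI covers the workflow but not workflow-manager integration;
  `--threads` is accepted for interface stability and currently ignored
  (all stages are single-pass and fast at desk scale).
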