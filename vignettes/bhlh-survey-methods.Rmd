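---
title: "Methods: genome-wide bHLH survey and classification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: genome-wide bHLH survey and classification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
library(bhlhscan)
```

This vignette documents the models and procedures behind `bhlhscan`, the
choices made where the design was genuinely open, and what the synthetic
benchmark does and does not demonstrate.

## The annotation problem

A bHLH survey of a draft genome answers three questions: *where* are the
loci encoding the ~60-residue basic helix-loop-helix domain, *are* the
candidate proteins genuine bHLHs, and *which* named ortholog family does
each belong to. The package decomposes this into a translated search, a
domain filter cascade, and a per-candidate phylogenetic assignment, with an
exon–intron structure module on the side. Every stage is deterministic
given its inputs; the only stochastic stages are the synthetic-data
generator and bootstrap resampling, both driven by explicit seeds.

## Translated genome search

Each reference domain sequence is aligned against all six translated
frames of every scaffold by exact affine-gap local alignment
(Smith–Waterman, implemented in C++). A gap of length $k$ costs
$g_{open} + (k-1)\,g_{ext}$; the defaults are BLOSUM62 with
$g_{open} = 10$, $g_{ext} = 1$, the conventional protein settings.
Alignments never cross stop codons or `N`-containing codons — the same
behavior as translated BLAST — so hits are confined to clean reading-frame
segments. Hits are extracted non-overlapping in descending score order:
one linear-memory forward pass records the best local score ending at each
subject position, score peaks above `min_search_score` (default 40) are
visited best-first, and each hit's alignment is recovered by a windowed
traceback (the subject span of a local alignment is bounded by its score
and the gap penalties).

Instead of BLAST e-values the search reports the raw score plus a
Karlin–Altschul-style `evalue_proxy` ($K m n e^{-\lambda S}$ with the
standard gapped-BLOSUM62 constants $\lambda = 0.267$, $K = 0.041$); the
score threshold is deliberately permissive because false loci are removed
downstream by the gene-model intersection and the domain filter, mirroring
a survey design that first collects all plausible genomic hits.

Hits are extended by `flank` bp on both sides (default 10,000, clamped to
the scaffold) and overlapping or touching intervals merge into candidate
loci; loci from different queries are merged as a plain interval union per
scaffold. Gene models come from GFF3 input (or the generator's truth); the
package deliberately does not predict genes, and provides only conceptual
translation of supplied models. Candidates on the same scaffold, strand
and reading frame whose coding regions overlap reciprocally by ≥ 0.8
collapse to the longest representative (ties to the leftmost), and every
filter decision — no domain hit, conserved-site failure, redundancy — is
recorded in an audit table.

## Domain detection and conserved sites

Candidate proteins are scanned with a position frequency profile built
from the reference domains; the position-specific score of residue $r$ at
frame column $j$ is $\sum_a f_a(j)\, B(a, r)$ with $B$ the substitution
matrix. A hit must cover at least half the motif frame (`min_coverage` =
0.5), which keeps high-scoring fragments much shorter than a domain out,
while still admitting the naturally occurring truncations in which the
basic region or helix 2 is missing.

Validation uses a table of conserved sites: frame columns with a set of
accepted residues. The packaged default lists 19 sites curated from the
canonical bHLH consensus (charged DNA-contacting residues in the basic
region, buried hydrophobics in the helices); a hit passes with ≥ 9
matching sites (`min_matches`), a gap never matches, and the table is an
editable TSV rather than a constant, because published surveys treat the
site list as a method parameter. `site_table_from_motifs()` derives a
table directly from a reference compendium (the most conserved columns,
with the residues observed there), which is what the synthetic benchmark
uses — the tests never depend on the curated literature values.

The motif frame is segmented as basic = columns 1–15, helix 1 = 16–30,
loop = 31–44, helix 2 = 45–60 (the basic region is ~15 residues; the
remaining boundaries divide the rest evenly and are configurable via
YAML). A region whose columns are all gapped is reported `missing`,
partially gapped `partial`; single-residue insertions are attached to the
region of their left anchor column.

## Tree inference

All tree building used by the cascade is implemented in the package:

* **Distances** — p-distance with pairwise deletion of gapped columns;
  optional gamma correction $d = \alpha\left((1-p)^{-1/\alpha} - 1\right)$.
  A pair with no comparable columns is an error naming the pair.
* **Neighbor joining** — Saitou–Nei agglomeration; equal $Q$ values are
  broken by the smallest index pair, so results are deterministic.
  Negative branch lengths are clamped to zero with the deficit absorbed by
  the sister edge (standard practice; the choice matters only for branch
  lengths, never the topology).
* **Parsimony** — Fitch small parsimony per column (gaps and ambiguity
  codes are wildcard state sets), vectorized over columns with integer
  bitmasks; tree search is best-improvement NNI hill climbing from the NJ
  starting tree. Hill climbing finds the global optimum reliably on
  alignments with real tree signal (verified against exhaustive 6-taxon
  enumeration); on signal-free data it can stop in a local optimum, which
  is the expected behavior of this class of search.
* **Bootstrap** — columns are resampled with replacement `reps` times (as
  integer column weights, so replicates reuse the encoded alignment); the
  support of each internal bipartition of the full-alignment reference
  tree is the percentage of replicate trees containing it, rounded to the
  nearest integer with .5 rounding up (supports are printed as integers).
* **Rooting and monophyly** — rooting places the root on the outgroup's
  pendant edge (via `ape`); supports are keyed by canonical leaf-set
  bipartitions and therefore survive rooting. The monophyly query returns
  the taxon's smallest enclosing non-trivial clade and that clade's
  support.

Maximum-likelihood and Bayesian inference are intentionally out of scope;
the cascade consumes per-method (ortholog, support) tuples, so externally
computed ML/Bayesian results can be supplied as additional rows of a
method-result table, exactly as the packaged catalog's four-method support
vectors are replayed in the tests.

## Ortholog assignment

For each candidate and reference set, the ingroup is the candidate, all
reference members of the putative family's high-order group (the group
ingroup mirrors published ingroup analyses; the putative family is the
best-scoring reference by global alignment), and the outgroup. When a
reference set is so small that a group holds a single member, the ingroup
widens to the whole set — a fallback that only matters for toy reference
sets. After progressive alignment (guide-tree profile–profile merging over
NJ of normalized pairwise alignment scores), each method's bootstrapped
tree is rooted at the outgroup and the candidate's sister set inspected:
an ortholog is reported only when the sister is exactly one reference
leaf.

The cascade per reference set, with threshold 50 (inclusive — the
published member counts require the inclusive reading) and majority
"strictly more than half":

1. every method names the same ortholog with support ≥ 50 → **assigned**;
2. more than half do → **assigned_majority**;
3. at least one method names an ortholog at any support → **tentative**;
4. otherwise the next reference set is consulted; after the last one the
   candidate is **lineage_specific**.

Paralogs within a family are numbered by descending best support, ties by
candidate id — the published catalogs do not state their numbering rule,
so the package fixes a deterministic one.

## The synthetic benchmark

The generator emulates the structure of a real survey: one root domain;
ortholog families evolved from it at `family_divergence` (default 0.8
substitutions/site — families are clearly separated but still alignable);
19 randomly placed conserved columns evolving at 2% of the base rate
(purifying selection, which is what makes conserved-site validation
meaningful); one member per reference species per family at `branch_rate`
0.05; candidates drawn from family ancestors at `candidate_divergence`
0.25, optionally with one extra domain residue (probability 0.1, mirroring
naturally observed single-residue insertions); substitution is uniform
replacement at exponentially distributed sites — no rate matrix, because
recovery testing needs divergence control, not realistic exchangeabilities.
Genes are back-translated with uniform synonymous codon choice, split into
1–6 exons at random codon boundaries with intron lengths log-uniform on
[35 bp, 1 Mb], and planted on one scaffold each (random strand, 2–10 kb
flanks) together with random-protein decoy genes. Defaults: 8 families, 2
reference species, 10 candidates, 3 decoys — a ~3–4 Mb genome that a
single CPU surveys in about a minute.

What passing the benchmark shows: the search, filter, tree and cascade
machinery recover planted truth exactly under realistic divergences, and
reject unrelated decoys. What it does not show: robustness to sequencing
error, fragmented assemblies, repeat content, alternative splicing, codon
bias, or rate heterogeneity beyond the frozen-site model — real-genome
performance still depends on curation of the reference compendium and the
site table.

## Numerical and scale choices

Alignment and search tie-breaks are fixed (traceback prefers diagonal,
then the query-consuming gap; equal-score search hits are taken leftmost),
so identical inputs give byte-identical outputs. Bootstrap seeds default
to 1000 and every API that consumes randomness takes an explicit seed; the
pipeline derives per-candidate and per-method streams by fixed offsets.

Problem sizes in the shipped tests and acceptance script are chosen for a
single CPU: 100 random additive matrices at up to 12 taxa; exhaustive
105-topology checks on ten 6-taxon alignments; brute-force alignment
enumeration up to length 6; 2000 bootstrap replicates for the binomial
comparison; and one end-to-end run at the default generator conditions
with 200 bootstrap replicates per method for the ingroup trees (the
low-level default of 1000 replicates reproduces the conventional
published protocol; 200 gives support resolution of half a percentage
point, ample for a threshold at 50). The full suite runs in under three
minutes.

## Known limitations

* Gene models must be supplied (GFF3 or generator truth); only a
  conceptual translation is performed, and cross-scaffold gene fragments
  are treated as separate models.
* Progressive alignment is a heuristic without iterative refinement; its
  pairwise projections are verified to stay within 20% of the pairwise
  optima on benchmark data, which suffices for ~60-residue domains but is
  not a general-purpose MSA guarantee.
* The NNI search does not implement SPR/TBR; for the small ingroups used
  by the cascade this is immaterial, and the exhaustive-enumeration tests
  bound its behavior.
* Supports from different methods are treated as comparable 0–100
  integers, as the published cascade does; mixing bootstrap proportions
  with posterior probabilities inherits that convention's caveats.
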