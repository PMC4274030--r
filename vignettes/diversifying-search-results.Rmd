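---
title: "Diversity-aware re-ranking of sequence search results: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diversity-aware re-ranking of sequence search results: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(divrank)
```

## The problem

A protein similarity search returns hits ordered by significance, and
significant hits tend to be mutual near-duplicates: if one close homolog
of a region scores well, dozens of its relatives do too. A user hunting
for *all* regions of a query with detectable relatives, or for
functionally distinct homologs, must page deep into the list. `divrank`
treats this as a search-result diversification problem: re-order the
finished result list greedily so that each added hit is as different as
possible, in its alignment to the query, from the hits already chosen.
Relevance is not recomputed — every fragment already passed the search
tool's significance filter — so the package diversifies only among hits
the tool itself returned.

## The star alignment

The unit of work is the *aligned fragment*: one HSP, i.e. one local
alignment of a database sequence to the query. A subject with several
HSPs contributes several independent fragments. All fragments are placed
on a common coordinate system anchored at the query: one column per
query position, plus insertion columns wherever some alignment put
subject residues between two query positions. When different hits insert
different numbers of residues after the same position, the column block
is sized by the longest run and shorter insertions are left-aligned and
gap-padded; this makes the coordinate system independent of hit order.

Within a fragment's HSP span, its row shows subject residues or `-` for
alignment gaps. Outside the span the row shows `.`, *non-aligned*, kept
distinct from the gap on purpose: a gap is evidence the alignment
considered and skipped a position, whereas non-aligned positions were
never part of the local alignment at all. The sequence-diversity measure
prices the two differently (below). The bit mask of a fragment is 1
where the row holds an amino acid and 0 for both `-` and `.`.
Coordinates are 1-based inclusive at every interface, the native
convention of both BLAST reports and R.

## Greedy diversification

Selection is seeded with the fragment the search tool ranked first — the
one hit whose relevance needs no defence — and grows one fragment per
step: every unchosen fragment is scored against the chosen set and the
highest scorer joins. Two scoring rules are shipped.

**Bit rule.** The difference between two fragments is the Hamming
distance of their bit masks (the popcount of their XOR), and a
candidate's score against the chosen set is the *average* of its
pairwise distances to the members — average linkage. Minimum (single)
and maximum (complete) linkage are available behind the `linkage`
argument, but average linkage is the default: single linkage lets one
similar member veto an otherwise novel candidate, complete linkage lets
one distant member excuse a redundant one.

**Entropy rule.** The candidate is scored by the total Shannon column
entropy of the alignment formed by the chosen set plus the candidate,
computed twice: over residue symbols (alphabet of 22: the 20 amino
acids, `-` and `.`) and over bits (alphabet of 2). Logarithms are base
2 throughout; the ratio below makes the base irrelevant. Each total is
normalized by the uniform-column upper bound, the number of columns
times log2 of the alphabet size — the tight bound attained when every
column spreads its rows evenly over the alphabet — and the two
normalized entropies are averaged. The residue level rewards amino-acid
variety at aligned positions; the bit level rewards coverage variety.
The query row itself is not included in the entropy: it is constant
across candidates and would shift every score equally.

Both rules are *incremental*: the top-`k` ranking is a prefix of the
top-`(k+1)` ranking, so `k` is a stopping point, not a parameter that
shapes the result. Ties in the per-step argmax go to the candidate with
the better original rank, preserving the search tool's relevance order;
scores within `1e-9` of the step maximum are treated as tied, which
absorbs floating-point summation-order noise (the smallest genuine score
gap at realistic problem sizes is larger by several orders of
magnitude, since both rules move in discrete composition steps).

Degenerate inputs behave predictably: a single fragment is returned
alone for any `k`; `k` larger than the fragment count returns all
fragments ranked; an empty fragment set is a contract error.

## Sequence diversity: Rao quadratic entropy

To *evaluate* a result set (not to drive the greedy loop — the two
selection rules are deliberately cheaper), the package scores the star
alignment with Rao's quadratic entropy. Per column,
$H = \sum_i \sum_j p_i p_j d_{ij}$, with $p$ the within-column symbol
frequencies over all rows and $d$ a symbol dissimilarity matrix; the
set's diversity is the mean over columns. $H = 0$ exactly when every
column is uniform, and $H$ never exceeds the largest pairwise distance.

The dissimilarity matrix comes from BLOSUM62. Each similarity is
replaced by its deficit from the row's self-similarity,
$a'_{ij} = a_{ii} - a_{ij}$; these raw deficits are asymmetric (the two
diagonals differ), so the final distance is the average
$(a'_{ij} + a'_{ji})/2$, giving a symmetric matrix with an exactly zero
diagonal. The matrix is then extended with the two alignment symbols:
the gap at `gap_distance` from every amino acid, and the non-aligned
symbol at *twice* the gap — never aligned is stronger evidence of
difference than a gap the aligner chose to open. The gap/non-aligned
pair sits at `gap_distance` (the geometric middle ground; no principled
value exists, so it is configurable). The default `gap_distance` of 9.5
places the non-aligned symbol at 19, which is the stated upper bound of
the BLOSUM62-derived distance matrix; both the gap distance and the
matrix itself are arguments everywhere they are used.

Two numerical cautions. First, the per-column probabilities always sum
to 1 because every row shows *some* symbol in every column (non-aligned
is a symbol); no renormalization is ever needed. Second, Rao's Q does
not satisfy the "twin property": duplicating one row of a set can
*increase* the measure when the duplicated row's symbols are distant
from a mutually-close remainder. This is a property of the index, not a
bug; only duplicating the entire set is guaranteed to leave the value
unchanged.

## Query coverage

Coverage is the fraction of true query positions (insertion columns
excluded) aligned by at least one chosen fragment. The coverage curve
evaluates this over ranking prefixes and is monotone by construction. A
`drop_first` flag excludes the seed fragment, useful when the query
itself is in the database and trivially tops the list.

## Functional diversity via the Gene Ontology

Functional evaluation uses Wang-style semantic similarity on the
molecular-function ontology. For a term $A$, every ancestor $t$ receives
an S-value: $S_A(A) = 1$ and
$S_A(t) = \max_{c \in \mathrm{children}(t)} w_e \cdot S_A(c)$ within
$A$'s ancestor DAG, where $w_e$ is an edge-type weight. The semantic
value $SV(A)$ is the sum of all S-values, and two terms compare as
$\mathrm{sim}(A,B) = \sum_{t \in \mathrm{common}} (S_A(t) + S_B(t)) /
(SV(A) + SV(B))$. The published weights 0.8 (is-a) and 0.6 (part-of)
are the defaults; molecular function has no part-of edges, so only the
first matters there. Protein-level similarity aggregates the cross-term
similarity matrix by best-match average (each term's best match on the
other side, averaged over both sides) — the aggregator is pluggable
(`max`, `average`) because the choice is a convention, not a theorem.
The functional dissimilarity of a result set is the mean over protein
pairs of one minus protein similarity, in $[0,1]$. Proteins without
molecular-function annotations are excluded (with a warning) before the
pairwise mean; fewer than two annotated proteins leaves the measure
undefined, which is reported as an error rather than a default value.

The OBO reader is intentionally minimal — `[Term]` stanzas, `is_a`,
`relationship: part_of`, namespace and obsolete flags — and refuses
cyclic graphs. Annotations load from GAF 2.x (aspect `F` rows, optional
IEA exclusion) or a plain two-column TSV. Evidence codes are not
filtered by default.

## The synthetic fixture generator

`generate_fixture()` emulates the structure that makes diversification
worthwhile: a query, `n_redundant` near-identical fragments piled on one
region (the first half when tilers are present, the whole query
otherwise), and `n_tilers` fragments tiling the remaining region with a
controlled overlap. Redundant fragments come first in report order,
mirroring a real search where the homolog pile outranks partial
matches. Substitutions are applied per residue at `mutation_rate`;
scores are twice the match count and e-values decay exponentially with
score. Defaults (query length 120, 8 redundant, 4 tilers, 10% overlap,
5% mutation) give a result set comfortably dominated by redundancy, the
regime the method targets. Output is deterministic in the seed, and the
session RNG state is restored afterwards.

What the generator does *not* emulate, and what passing tests therefore
do not show about real data: alignments are gapless (insertion-column
handling is exercised by hand-built alignments instead), there are no
paralog families at intermediate identity, no length-dependent score
statistics, no compositional bias, and subject sequences exist only as
their aligned fragments. The generator validates the machinery, not the
biology.

## Problem sizes and test design

The oracle-equivalence suite checks both greedy rules against a plain
per-step brute-force argmax, and the Rao measure against a direct
double-loop evaluation, on 200 generated fixtures with at most 15
fragments and 40 query columns — small enough that the brute force is
unarguably correct and the whole suite runs in well under a minute.
Prefix/incrementality is asserted for every `k` on 15 fixtures per rule,
and coverage dominance (the diversified ranking reaches full query
coverage with a prefix no longer than the original order needs) on 100
cluster-plus-tiler fixtures. GO arithmetic is frozen against
hand-evaluated chains and diamonds on a toy DAG. The bundled BLOSUM62
file is cross-checked against the Biostrings copy, and column entropies
against `vegan::diversity`.

## Known limitations

* The entropy rule's normalization uses the uniform upper bound; any
  other monotone normalization would produce the same *ranking*, but the
  reported selection scores would differ.
* Whether the seed should be the first subject or the first fragment
  when the top subject has several HSPs is a convention; the package
  seeds with the first fragment in report order.
* Rao diversity inherits the twin-property violation discussed above;
  comparisons between result sets of very different sizes should use
  the coverage curve alongside it.
* The GO machinery assumes the annotation file's identifiers match the
  result set's subject identifiers; no accession mapping is attempted.
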