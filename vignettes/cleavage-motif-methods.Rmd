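---
title: "From labeled peptides to predicted substrates: methods and design"
author: "CleaveScan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{From labeled peptides to predicted substrates: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(CleaveScan)
```

## The model

CleaveScan treats protease substrate recognition as a short linear motif
problem. A motif is an ordered list of position specifications in the
PROSITE dialect: residue classes `[LIMV]` (one residue from the set),
exclusion classes `{G}` (one standard residue not in the set), and
bounded wildcards `X`, `X(n)`, `X(m,n)` (a run of unconstrained
residues). The general calpain-3 cleavage motif is the canonical
example: a 10-residue frame with aliphatic key residues at positions 1,
6 and 9 and an acidic residue at position 10, everything else backbone.

The assumptions are those of any linear-motif analysis: recognition is
decided by the primary sequence within the frame, positions contribute
independently (a position is a set of allowed residues, not a weight
matrix), and a single site suffices to call a protein a candidate
substrate. Context the model deliberately ignores — surface exposure,
secondary structure, tissue co-expression — is exactly what downstream
experiments must supply.

## Matching semantics

`matchAt`, `scanSequence` and `scanDatabase` follow ScanProsite
conventions, which the package treats as part of the contract:

* Coordinates are 1-based and inclusive in every report.
* **Not greedy** (default): wildcard runs try their shortest extent
  first, earlier wildcards varying most significantly, and the first
  full-pattern success is returned. `greedy = TRUE` is the exact
  reverse order.
* **No overlap** (default): after a hit ending at `e`, scanning resumes
  at `e + 1`; with `overlap = TRUE` every matching offset is reported.
* Ambiguity and non-standard codes (B, J, O, U, X, Z) match wildcards
  but never classes or exclusions. This is the conservative choice — an
  uncertain residue never creates a hit. `strictExclusions = FALSE`
  relaxes exclusion classes to "anything not listed" for callers who
  prefer the permissive reading.
* Splice-variant expansion is out of scope: the scanner sees exactly
  the FASTA records it is given.

`violations` aligns a whole peptide against the whole pattern and
reports every constrained position whose residue fails, as 1-based
residue coordinates within the frame (the motif's "site" numbering).
For variable-span patterns all span assignments consuming the peptide
are evaluated; the one with fewest violations wins, ties resolved
toward earlier wildcards taking shorter extents. This is what localizes
the uncleaved AHNAK-repeat peptide's single defect at position 9.

## Discovery: `<L,W,K>` patterns

`discoverPatterns` reimplements the TEIRESIAS decomposition at desk
scale. A pattern over the discovery alphabet (wildcard, equivalence
group, literal) is `<L,W>`-valid when every run of exactly `L`
consecutive non-wildcard elements spans at most `W` columns; a reported
pattern occurs in at least `K` sequences and is *maximal*: no more
specific or longer valid pattern retains all of its occurrences.

* The scan phase (`enumerateElementary`) exhaustively enumerates
  patterns with exactly `L` non-wildcard elements, including literal
  specializations that keep support.
* The convolution phase (`convolvePatterns`) merges patterns whose
  columns are compatible, intersects their occurrence lists (support is
  therefore always exact), and closes every pattern under
  agreement-preserving specialization and extension. When
  `<L,W>`-validity forbids adding all agreeing columns at once, all
  maximal valid column subsets are emitted, so ties in maximality are
  kept rather than broken arbitrarily.
* Ranking is by support (descending), then number of constrained
  elements (descending), then span (ascending), then pattern text —
  fully deterministic.

The default equivalence grouping partitions the 20 residues by chemical
property (aliphatic LIMV, acidic DE, basic KR, aromatic FYW, hydroxyl
ST, amide NQ, small AG, and singletons C, P, H). It was chosen so that
the classes appearing in the published motif are expressible; any
partition can be supplied instead. Support counts distinct sequences by
default ("number of proteins"); `supportMode = "occurrence"` counts
sites instead, since a panel can contain several sites per protein.
None of TEIRESIAS's performance engineering (prefix trees, offset-list
compression) is reproduced: correctness at panel scale is the contract,
and the test suite holds the implementation to exact agreement with an
exhaustive oracle on small corpora (up to a dozen sequences of length
about eight over reduced alphabets — sizes at which exhaustive
enumeration is still tractable as an independent reference).

## Refinement: unions, wildcards, exclusions

`refineMotif` composes three steps, all deterministic:

* `alignPeptides` anchors every peptide at frame positions 1 and 10.
  Full-length peptides map one residue per column; peptides one residue
  short gap at the variable-spacing column (default 5, matching the
  printed `X(0,1)` placement). Lengths that differ by more than one
  cannot be reconciled with a single bounded gap and error.
* `buildUnionMotif` takes, at each column, the union of residues seen
  in positive peptides. Partially cleaved peptides count as positives
  by default (`includePartial = FALSE` excludes them), since the
  published stringent motif demonstrably pooled residues from them. A
  column whose union reaches `diversity_threshold` residues (default 7)
  is considered unconstrained backbone and becomes a wildcard; the
  published construction converts a site to an exclusion without
  stating a rule, and 7 — one more than the largest printed class —
  is the package's explicit, configurable cut. Gapped columns become
  `X(0,1)`.
* `addExclusions` turns a wildcard column into an exclusion class for
  residues observed there in not-cleaved peptides but never in
  positives — the route by which glycine, present at site 4 only in
  dysfunctional peptides, becomes `{G}`.

`jackknifeContribution` quantifies how much each construction peptide
accounts for the result: the motif's classes form a set of
(position, residue) pairs, and a peptide's contribution is the fraction
of pairs its own residues support. The mean over peptides is 1 exactly
when all peptides are identical and decreases as the classes pool
diversity. The published analysis reports a mean contribution without
stating its formula, so this operational definition is the package's
own and its numeric value is not comparable across definitions.

## Enrichment: hypergeometric information content

Annotations follow the true-path rule (`propagateAnnotations` computes
the is_a ancestor closure; it is idempotent). Each namespace is
evaluated against its own root: with `N` background proteins at the
root, `n` of them substrates, and a term annotated to `K` background
and `k` substrate proteins, the term scores

$$p = P(X \ge k), \quad X \sim \mathrm{Hypergeometric}(N, K, n),
\qquad \mathrm{ic} = -\log p .$$

The upper tail is the standard over-representation reading; a
point-probability mode sits behind `point = TRUE`. The log base
defaults to natural and is configurable (and recorded in output
headers) — it scales the information content but never changes the
ranking. The root term of every namespace scores `p = 1`, `ic = 0`, by
construction. Ranking is by information content, not by adjusted
p-values; a Benjamini–Hochberg column is emitted for convenience only.
An information-content cutoff (`ic_cut`) truncates the report the way
the published table was cut, and is dataset-specific rather than a
package default.

The OBO reader supports the minimal subset the pipeline needs —
`[Term]` stanzas with `id`, `name`, `namespace`, `is_a`, obsolete terms
skipped — and validates acyclicity and a single root per namespace. No
installed package provides OBO parsing in this stack, so the parser is
part of the enrichment module.

## Synthetic data and what passing tests mean

The generators are the package's benchmark instruments, all
seed-deterministic:

* `generateProteome` draws iid residues (uniform by default; a
  vertebrate-like composition table ships as an alternative). Real
  proteomes have length and composition structure these sequences lack.
* `plantMotifs` samples instances uniformly from a pattern's language
  and overwrites them at recorded, non-overlapping coordinates
  (rejection sampling, 1000 attempts). Overwriting rather than
  inserting keeps all coordinates stable.
* `samplePeptidePanel` emulates a labeled assay panel: positives from
  the pattern language, negatives with one key position mutated to a
  disallowed residue, the site recorded.
* `generateOntologyAnnotations` builds a single-namespace DAG, anchors
  every protein at the root, gives every non-root term background
  annotations at `p_out`, and annotates the designated leaf at `p_in`
  on substrates. Because ancestors inherit their children's
  annotations under propagation, an ancestor of the planted leaf can
  legitimately rank above it; the planted guarantee is that the
  enriched leaf and its ancestors dominate the top of the ranking.
* `expectedMatchRate` is the analytic per-offset hit probability under
  an iid background — the sum over span assignments of per-position
  acceptance probabilities. For fixed-span patterns (the general motif:
  $(4/20)^3 \times (2/20) = 8 \times 10^{-4}$) this is exact; for
  variable-span patterns assignments overlap as events and the sum is a
  tight upper approximation.

Passing tests on these fixtures demonstrate algorithmic correctness —
the scanner equals a brute-force matcher, discovery equals exhaustive
enumeration, planted signals are recovered — not biological accuracy on
real proteomes, where composition bias, domain structure and database
versions move all hit counts.

## Numerical and degenerate-input choices

* Patterns with only wildcards are representable (`parsePattern("X")`
  works, matching trivially); every discovery or refinement output
  carries at least one constrained position.
* A pattern's span assignments are enumerated explicitly and capped at
  10,000 combinations; the dialect's motifs have at most a handful.
* Empty sequences scan to empty hit tables; an empty substrate set
  enriches to an empty report; a panel with no negatives leaves the
  motif unchanged.
* `hypergeomTail(0, ...)` is exactly 1, and `informationContent(1)` is
  exactly 0, so root rows are 0 without floating-point noise.
* All tie-breaks (violation alignments, discovery ranking, enrichment
  row order) are specified and deterministic, so identical inputs give
  byte-identical outputs.

## Problem sizes used in the test suite

The suite verifies the scanner against 1000 random pattern/sequence
pairs (sequences up to 120 residues), discovery against exhaustive
oracles on corpora of up to 12 sequences of 6–8 residues, scan
statistics on a $10^6$-residue background (binomial 3-sigma agreement
with the analytic rate), refinement recovery on panels of 20–30
positives with 5 single-site negatives, and the hypergeometric tail
against complete subset enumeration for every admissible configuration
with $N \le 12$. These sizes were chosen as the smallest at which the
independent oracles are themselves beyond doubt.

## Known limitations

* Only the PROSITE constructs the cleavage-motif dialect uses are
  parsed; terminal anchors (`<`, `>`) and class repetition are not.
* The refinement frame is a single anchored frame with one bounded gap
  column; peptides shorter by two or more residues are rejected rather
  than multiply gapped.
* Discovery is exponential in the worst case and intended for peptide
  panels and small corpora, not whole proteomes.
* The jackknife contribution is one defensible formalization among
  several; compare values only within this package.
* The enrichment module handles is_a edges only (no part_of or
  regulates), and applies no multiple-testing correction to its
  headline ranking by design.
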