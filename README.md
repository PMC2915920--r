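# CleaveScan

Protease cleavage-motif discovery, refinement and proteome-wide substrate
prediction, with ontology-based characterization of the predicted
substrate set.

## The problem

Calpain 3 (CAPN3) is the muscle-specific calcium-dependent cysteine
protease whose loss causes limb-girdle muscular dystrophy type 2A. Its
known substrates share a short linear recognition motif at the cut site:
a 10-residue frame in which only four positions are constrained ("key
residues") while the backbone tolerates almost any residue:

```
[LIMV]-X(4)-[LIMV]-X(2)-[LIMV]-[DE]
```

i.e. aliphatic residues at frame positions 1, 6 and 9 and an acidic
residue at position 10. CleaveScan reimplements the computational route
from a panel of peptides labeled by a cleavage assay to proteome-wide
substrate prediction:

1. **Discovery** (`discoverPatterns`) — TEIRESIAS-style `<L,W,K>` pattern
   discovery over a chemical-equivalence alphabet: every maximal pattern
   with at least `L` constrained elements, no `L` of which span more than
   `W` columns, occurring in at least `K` input sequences.
2. **Refinement** (`refineMotif`) — anchored alignment of labeled
   peptides into the 10-position frame, position-wise residue union over
   cleaved peptides, conversion of over-diverse positions to wildcards,
   and exclusion classes (e.g. `{G}`) at positions where only uncleaved
   peptides carry a residue; jackknife contribution statistics
   (`jackknifeContribution`) measure how much any one construction
   peptide accounts for the motif.
3. **Scanning** (`scanSequence`, `scanDatabase`) — PROSITE-dialect
   matching with ScanProsite-compatible semantics (1-based inclusive
   coordinates, no-overlap and not-greedy defaults, bounded wildcards
   `X(m,n)`, exclusion classes `{..}`).
4. **Enrichment** (`enrichTerms`) — for the predicted substrate set,
   each ontology term annotated to `k` of `n` substrates and `K` of `N`
   background proteins (after true-path propagation, per namespace)
   scores the upper-tail hypergeometric probability
   `p = P(X >= k)` and an information content `-log p`; the namespace
   root always scores 0.

A synthetic-data module (`generateProteome`, `plantMotifs`,
`samplePeptidePanel`, `generateOntologyAnnotations`,
`expectedMatchRate`) generates proteomes with planted motif instances,
labeled panels from a known generating pattern, and toy ontologies with
a controlled enriched term, all with recorded ground truth.

## Worked example

```r
library(CleaveScan)

general <- parsePattern("[LIMV]X(4)[LIMV]X(2)[LIMV][DE]", name = "general")
spanRange(general)
#> min_len max_len
#>      10      10
keyPositionCount(general)
#> [1] 4

## the built-in substrate peptide panel: 13 motif-bearing peptides plus
## the uncleaved AHNAK-repeat peptide
panel <- substratePanel()
matchAt(general, "VPSANIEGLE", 1)   # AHNAK-N peptide
#> [1] 10
violations(general, "VPDVSLEGPE")   # AHNAK-repeat peptide
#>   position observed
#> 1        9        P
```

The uncleaved peptide fails the motif at exactly one key position —
position 9, where it carries a proline instead of an aliphatic residue —
which is why it is not a substrate although it is otherwise homologous
to a cleaved peptide. Rediscovering the motif from the panel:

```r
top <- discoverPatterns(panel$sequence, L = 4, W = 10, K = 13)[[1]]
discoveredString(top)
#> [1] "[LIMV]X(4)[LIMV]X(2)[LIMV][DE]"
top@support
#> [1] 13
```

Scanning a database and characterizing the hits:

```r
hits <- scanDatabase(general, "proteome.fasta")
hits$protein_count          # proteins carrying at least one site
er <- enrichTerms(unique(hits$hits$sequence_id), onto, annotations)
head(er)                    # terms ranked by information content
```

An end-to-end run (`runPipeline`) chains refine → scan → enrich and
writes TSV outputs with provenance headers; a thin command-line wrapper
with `scan`, `discover`, `refine`, `enrich`, `simulate` and `pipeline`
subcommands is installed at `inst/scripts/cleavescan.R`.

## Scope

CleaveScan operates at desk scale on caller-provided FASTA, TSV and OBO
inputs. It does not download UniProt or GO releases, does not expand
splice variants, and does not reproduce wet-lab assays, mass
spectrometry, structure prediction or literature-mining analyses.
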