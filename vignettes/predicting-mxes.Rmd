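---
title: "Predicting mutually exclusive exons from annotated genomes"
author: "mxefinder"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting mutually exclusive exons from annotated genomes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mxefinder)
```

## The biological model

Mutually exclusive exons (MXEs) are clusters of neighbouring exons of which
exactly one is spliced into each mature transcript.  Well-studied examples —
the arthropod muscle myosin heavy chain gene, *DSCAM*, the 14-3-3ζ gene —
show that the members of a cluster encode the *same* region of the protein:
they substitute for one another in the folded structure.  That premise fixes
four testable preconditions for any candidate alternative exon:

1. **Conserved splice sites.**  On the coding strand an internal exon is
   preceded by an `AG` acceptor and followed by a `GT` (or the minor `GC`)
   donor.
2. **Reading-frame preservation.**  Substituting one exon for another must
   not shift the frame of all downstream exons, so the candidate's length
   must differ from the original exon's by a multiple of three nucleotides.
3. **Similar length.**  Helices and strands tolerate little length change;
   loops tolerate some.  The length difference in amino acids is bounded.
4. **Sequence homology.**  The candidate's encoded peptide must align to the
   original exon's peptide.

`mxefinder` turns these preconditions into an exhaustive search over the
introns (and optionally the flanks) of every annotated coding gene.

## The similarity score

For an original exon peptide $o$ and a candidate peptide $c$ the similarity
score is

$$ S(o, c) \;=\; 100 \cdot \frac{\mathrm{align}(o, c)}{\mathrm{align}(o, o)} $$

in percent, where $\mathrm{align}$ is a *global* pairwise alignment score
(end gaps penalized) under BLOSUM62 with affine gap penalties — a gap of
length $L$ costs $11 + L$.  Identical peptides score exactly 100; unrelated
peptides usually score negatively.  Global alignment is the right regime
because cluster members are presumed to encode the same region end-to-end;
local alignment would reward spurious short matches.  The matrix and both
gap penalties are configurable through `predictionParams()`; the alignment
itself is computed by `Biostrings::pairwiseAlignment`, and the test suite
cross-checks it against an independently written Gotoh dynamic-programming
aligner to $10^{-9}$.

## Parameters and the two presets

| parameter | display | store | meaning |
|---|---|---|---|
| `minScore` | 15 % | 10 % | minimum similarity score |
| `maxLenDiff` | 20 aa | 20 aa | maximum length difference |
| `minExonLen` | 15 aa | 10 aa | minimum original exon length |
| `scope` | flanking | all | introns searched per source exon |
| `flankNt` | 0 | 20,000 | nt of up-/downstream flank searched |

The *store* preset is deliberately relaxed: a prediction run stores every
candidate that could ever be of interest, and the *display* filters are then
applied as pure predicates on stored fields (`applyFilters()`,
`filterResult()`).  Re-filtering therefore never re-runs the search, and the
YAML master output is written at full numeric precision (17 significant
digits) so that a filtered set recomputed from the YAML alone is
bit-identical to the in-memory one.

Two further knobs are design choices the sources of this method leave open:

* `minCandidateMargin` (default 20 nt) — a candidate must keep this distance
  from each edge of its search region, preventing degenerate zero-length
  residual introns.
* Overlap resolution — among mutually overlapping raw candidates in one
  region only the best is reported (highest score, then smaller length
  difference, then 5'-most start).  Without this rule every planted exon
  would drag along a tail of truncated sub-candidates sharing its splice
  sites.

## Search regions and location classes

Each original exon of at least `minExonLen` amino acids seeds a search of
its upstream and downstream introns (`scope = "flanking"`) or of all introns
(`scope = "all"`); with `flankNt > 0` the windows up- and downstream of the
*gene locus* are searched too, which identifies candidates for partial genes
and, as a by-product, ordered copies of several exons that indicate tandem
gene duplicates or trans-spliced genes (`flagTandemOrTrans()`).  Candidates
are labelled `upstream_intron`, `downstream_intron`, `other_intron`,
`upstream_flank` or `downstream_flank` relative to their source exon; the
display scope keeps only the flanking-intron classes.  In flank regions the
splice-site requirement is lifted on the gene-distal side of initial and
terminal source exons, which lack an acceptor and a donor respectively.

## Stop codons, phases and junction codons

Candidates are translated in the frame imposed by the source exon's start
phase.  Any stop codon among the candidate's complete codons rejects it,
except a stop in the final codon when the source exon is the terminal exon
(whose original carries the stop itself).  Codons split across a splice
junction are attributed to the upstream exon for display (so concatenated
display peptides reproduce the full CDS translation — a tested invariant),
but scoring uses only each exon's complete codons: a replacement exon
changes a junction codon's identity only through its own sequence, which the
score already captures.  `aa_len` is `floor(nt_len / 3)`, a conservative,
integer-stable convention for partial codons.

## Gene models and validation

Gene models are reconstructed from a genome FASTA plus a GFF3 annotation
(gene → mRNA → CDS).  Internally all coordinates are 0-based half-open on
the forward strand; GFF3 (1-based inclusive) and BED (0-based half-open) are
converted only at format boundaries.  `validateStructure()` labels — it
never rejects — introns that do not match `GT...AG`/`GC...AG`, internal
stops, a missing terminal stop, phase-chain inconsistencies and (when a
protein FASTA is supplied) translation mismatches; any label marks the
isoform *incomplete*.  Incomplete isoforms are still searched: partial genes
are precisely where flank search earns its keep.

## Clusters, annotated MXEs and sensitivity

Every source exon and its surviving candidates form a cluster; clusters
sharing a member interval, or whose source exons mutually predict each
other, are merged by transitive closure (`assembleClusters()`).  A cluster
containing any isoform's first coding exon is *initial* (multiple
promoters), one containing a last coding exon is *terminal* (multiple
poly(A) sites), anything else *internal*; a two-exon isoform qualifying as
both is labelled initial — an arbitrary but deterministic tie-break that is
logged.

Annotated MXE clusters are detected from the annotation alone: maximal
groups of ≥ 2 neighbouring, non-overlapping exons such that *every* isoform
contains exactly one member (`detectAnnotatedMXEClusters()`).
"Neighbouring" means no annotated exon of any isoform lies strictly between
members — the weakest definition consistent with the worked example below.
An isoform containing two members (a cassette pattern) or none disqualifies
the group; tolerating skipping isoforms would be a different, laxer
definition and is deliberately not the default.  Neighbouring exons of one
isoform that pairwise meet all MXE criteria are reported separately as
*MXE-like constitutive exons* (`detectConstitutiveMXELike()`); their
pairwise score is computed in both directions and the better one used,
since neither exon is privileged as "the original".

Sensitivity is the fraction of annotated (by default internal-cluster)
MXEs whose genomic interval is exactly reconstructed by a candidate sourced
from a different exon of the same cluster (`computeSensitivity()`).  Exact
boundary match is the strictest reading of "reconstructed" and the default.

## The synthetic-data generator

`generatePlantedGenome()` builds deterministic genomes whose ground truth is
known by construction: random coding genes (ATG start, single terminal
stop, canonical introns), planted alternative exons that are
amino-acid-level mutated copies of their source exon at a requested
identity (substitution count is exact, so realized identity is within
rounding of the target; indels act on whole codons), multi-isoform
annotation patterns (annotated-MXE and cassette), and optional ordered
flank duplications.  Exon boundaries are codon-aligned at pattern and plant
source exons — so alternative inclusion preserves the frame by
construction — and carry random phase offsets elsewhere to exercise phase
propagation.

Intergenic and padding sequence is i.i.d. uniform nucleotides, which is the
generator's main departure from real genomes: no codon-usage bias, no
GC-content structure, no realistic splice-site strength distribution, no
repeats.  Passing tests on these genomes therefore demonstrate the
correctness of the search algebra (enumeration, filtering, clustering,
bookkeeping), not the false-positive rate to be expected on real genomes.
To make negative controls exact, every generated intron is screened with
the package's own enumerator at the relaxed store parameters and its random
padding is resampled until no chance candidate survives — so a genome
without plants yields zero candidates by construction, and recovery tests
measure the search, not the generator's luck.

The worked-example fixture (`fig2bFixture()`) is a three-exon gene whose
18-aa middle exon has three engineered alternatives: `2a` (upstream intron,
length difference 12 aa) and `2d` (downstream intron, 13 aa) score well
above the display threshold, while `2c` (downstream intron, same length) is
degraded by deterministic greedy substitution until its score falls in
[10, 15) — found by the relaxed store stage, removed by the default display
score.  Its constraints are checked by assertions at construction time.
When a single filter is varied in the tests, the remaining filters are held
at the relaxed store values so each rule's effect is observed in isolation.

```{r fig2b}
fx <- fig2bFixture()
model <- buildGeneModels(fx$annotation, fx$genome)[[1]]
store <- predictGene(model, fx$genome, predictionParams("store"))
store[, c("sourceExonIndex", "location", "start", "end", "lenDiffAa", "score")]
applyFilters(store, predictionParams())$report
```

## Numerical and degenerate-input choices

* Ambiguous bases (`N`): candidates spanning an `N` are skipped with a
  warning; scores over ambiguous residues are undefined, and wildcard
  scoring would silently inflate similarity.
* Empty peptides or a non-positive self-alignment score raise errors — a
  degenerate original exon cannot normalize a score.
* Candidate ordering is fully deterministic (source isoform, source exon,
  location class 5'→3', genomic start), so identical inputs give
  byte-identical outputs.
* Overlap-resolution ties break by smaller length difference, then 5'-most
  start.
* Minus-strand genes are handled by mirroring coordinates, never by
  reverse-complementing the whole analysis; a strand-symmetry test checks
  that predictions on a reverse-complemented genome are coordinate mirrors.

## Problem sizes used by the test suite

The suite validates enumeration against a literal $O(n^2)$ brute force on
50 random introns of up to 2 kb; planted recovery on 100-gene genomes (two
alternatives per gene at 80% and at 100% identity); negative controls on
100 plant-free 5-gene genomes; and the score contract on 100 random peptide
pairs.  These sizes were chosen so the whole suite demonstrates every claim
on a single CPU in a few minutes while keeping each check statistically
meaningful.

## Known limitations

* Standard nuclear genetic code only; organism-specific codes are out of
  scope.
* No probabilistic splice-site models (MaxEnt-like), no branch-point
  detection, no U12 introns: splice sites are the literal dinucleotides.
* Specificity on real genomes cannot be estimated from these tests (that
  would require a perfectly annotated genome); the sensitivity machinery
  only measures recovery of annotated or planted truth.
* Trans-spliced multi-locus gene reconstruction is not attempted; ordered
  flank copies are merely flagged.
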