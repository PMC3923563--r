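# mxefinder

Prediction of mutually exclusive exons (MXEs) in annotated eukaryotic
genomes.

## The problem

Mutually exclusive splicing includes exactly one exon out of a cluster of
neighbouring exons in each mature transcript.  Because the members of such a
cluster encode the same region of the protein (the classic cases are the
arthropod muscle myosin heavy chain and *DSCAM* genes), they obey strong,
testable constraints: conserved splice sites (`AG` acceptor before,
`GT`/`GC` donor after, on the coding strand), preservation of the reading
frame (length difference a multiple of 3 nt), similar length, and peptide
homology.  Annotation databases systematically under-report these exons —
many sit unannotated in introns, or are mislabelled as constitutive.

`mxefinder` is for genome annotators and alternative-splicing researchers:
given a genome FASTA and a coding-gene GFF3, it reconstructs validated gene
models and exhaustively scans introns (and optionally gene flanks) for exon
candidates that satisfy all four constraints, then filters, clusters,
classifies and summarises them.

## The score at the core

A candidate's similarity to its source exon is

```
score = 100 * align(original, candidate) / align(original, original)   [%]
```

with `align` a global (end-gap-penalized) peptide alignment under BLOSUM62,
gap open 11, gap extend 1.  Identical peptides score exactly 100; unrelated
ones usually score negatively.  Candidates must also satisfy
`(len_cand − len_orig) mod 3 == 0`, a length difference of at most 20 aa,
and carry no stop codon in the source exon's frame.

Predictions are made with deliberately relaxed *store* parameters
(score ≥ 10 %, original exon ≥ 10 aa, all introns, ±20 kb flanks) and then
reduced by strict *display* filters (score ≥ 15 %, exon ≥ 15 aa, flanking
introns only) — filtering is pure, so stored predictions can be re-filtered
with any thresholds without re-running the search.

## Worked example

The package ships a deterministic three-exon example gene whose
18-amino-acid middle exon (2b) has three engineered alternatives: 2a in the
upstream intron, 2c and 2d in the downstream intron.

```r
library(mxefinder)

fx <- fig2bFixture()
model <- buildGeneModels(fx$annotation, fx$genome)[[1]]
store <- predictGene(model, fx$genome, predictionParams("store"))
store[, c("sourceExonIndex", "location", "start", "end", "lenDiffAa", "score")]
#>  sourceExonIndex          location start end lenDiffAa score
#>                2   upstream_intron   367 457        12    77
#>                2 downstream_intron   612 666         0    14
#>                2 downstream_intron   699 792        13    76
```

All three candidates derive from exon 2b.  The first and third (2a, 2d)
are 12 and 13 codons longer than the original and align at 77 % and 76 %;
the middle one (2c) has the original length but only 14 % similarity.
Applying the display filters removes exactly 2c, and the report names the
rule that removed it:

```r
applyFilters(store, predictionParams())$report
#>                             candidateId  pass firstFail
#>    g2b|g2b.1|e2|upstream_intron|367-457  TRUE      <NA>
#>  g2b|g2b.1|e2|downstream_intron|612-666 FALSE     score
#>  g2b|g2b.1|e2|downstream_intron|699-792  TRUE      <NA>
```

At the store stage the source exon and its three alternatives assemble into
one cluster of four, classified internal (it contains neither a first nor a
last coding exon):

```r
cl <- assembleClusters(model, store)[[1]]
members(cl)[, c("start", "end", "provenance", "score")]
#>  start end     provenance score
#>    367 457  predicted_new    77
#>    527 581 annotated_exon    NA
#>    612 666  predicted_new    14
#>    699 792  predicted_new    76
clusterType(cl)
#> [1] "internal"
```

Whole-dataset runs go through `predictMXE()`, which also reconciles
candidates across isoforms and neighbouring genes, detects MXE clusters
already present in the annotation, flags MXE-like constitutive exons, and
produces a summary table; `writeResults()` emits YAML (lossless master),
TSV, GFF3 and BED.  `generatePlantedGenome(plantSpec(...))` builds
deterministic synthetic genomes with planted clusters and known ground
truth.  A thin command-line wrapper with `predict`, `filter`, `stats` and
`simulate` subcommands lives at `inst/scripts/mxefinder-cli.R`.

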