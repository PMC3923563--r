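# helpers building tiny annotated genomes in code
makeGenome <- function(seq) Biostrings::DNAStringSet(c(chr1 = seq))

annRow <- function(geneId, proteinId, start, end, strand = "+", phase = NA) {
  data.frame(geneId = geneId, proteinId = proteinId, targetId = "chr1",
             start = start, end = end, strand = strand,
             phase = as.integer(phase), stringsAsFactors = FALSE)
}

test_that("exonPeptide translates complete codons with phase skip", {
  expect_equal(exonPeptide("ATGGCC", 0), "MA")
  expect_equal(exonPeptide("AATGGCC", 1), "MA")
  expect_equal(exonPeptide("ATGGC", 0), "M")     # trailing partial dropped
  expect_equal(exonPeptide("TA", 0), "")
  expect_equal(exonPeptide("TAAGCC", 0), "*A")   # stop rendered as *
  expect_error(exonPeptide("ATGN", 0), "outside A,C,G,T")
})

test_that("exonPeptide agrees with an independent codon-table translator", {
  set.seed(101)
  for (k in 1:25) {
    nt <- paste(sample(c("A", "C", "G", "T"), 300, TRUE), collapse = "")
    for (ph in 0:2)
      expect_equal(exonPeptide(nt, ph), oracleTranslate(nt, ph))
  }
})

test_that("single-exon gene builds one complete isoform without introns", {
  cds <- paste0("ATG", "GCCGGG", "TAA")
  g <- makeGenome(paste0("CCCC", cds, "GGGG"))
  ann <- annRow("g1", "g1.1", 4, 4 + nchar(cds))
  m <- buildGeneModels(ann, g)[[1]]
  iso <- isoforms(m)[[1]]
  expect_equal(nrow(introns(iso)), 0)
  expect_equal(completeness(iso), "complete")
  expect_equal(exons(iso)$peptide, "MAG*")
})

test_that("phase propagates through the chain: 100 nt phase-0 exon yields phase 2", {
  # two-exon gene; exon1 100 nt starting at phase 0 -> exon2 phase (3-100%%3)%%3 = 2
  set.seed(5)
  exon1 <- paste0("ATG", paste(sample(c("GCC", "GAA", "CTG", "AAA"), 33,
                                      TRUE), collapse = ""))
  exon1 <- substr(paste0(exon1, "C"), 1, 100)
  exon2 <- paste0("CT", paste(rep("GCA", 10), collapse = ""), "TAA")
  intron <- paste0("GT", paste(rep("A", 40), collapse = ""), "AG")
  g <- makeGenome(paste0("CC", exon1, intron, exon2, "CC"))
  ann <- rbind(annRow("g1", "g1.1", 2, 102),
               annRow("g1", "g1.1", 146, 146 + nchar(exon2)))
  iso <- isoforms(buildGeneModels(ann, g)[[1]])[[1]]
  expect_equal(exons(iso)$startPhase, c(0L, 2L))
})

test_that("reconstructed peptides equal the generator's planted proteins", {
  spec <- plantSpec(nGenes = 100, exonsPerGene = c(2, 4),
                    exonAaLen = c(15, 30), intronLen = c(80, 150),
                    intergenicNt = 120, minusStrandProb = 0.4, seed = 303)
  g <- generatePlantedGenome(spec)
  models <- buildGeneModels(g$annotation, g$genome, proteins = g$proteins)
  expect_length(models, 100)
  okCount <- 0
  for (m in models) {
    iso <- isoforms(m)[[1]]
    expect_equal(completeness(iso), "complete")
    full <- paste(exons(iso)$displayPeptide, collapse = "")
    if (identical(sub("\\*$", "", full),
                  as.character(g$proteins[[iso@proteinId]])))
      okCount <- okCount + 1
  }
  expect_equal(okCount, 100)
})

test_that("structural validation flags splice sites, stops and mutations", {
  exon1 <- paste0("ATG", paste(rep("GCA", 12), collapse = ""))
  exon2 <- paste0(paste(rep("CTG", 12), collapse = ""), "TAA")
  mkGene <- function(donor = "GT", acceptor = "AG", exon2. = exon2) {
    intron <- paste0(donor, paste(rep("T", 30), collapse = ""), acceptor)
    makeGenome(paste0("CC", exon1, intron, exon2., "CC"))
  }
  ann <- rbind(annRow("g1", "g1.1", 2, 2 + nchar(exon1)),
               annRow("g1", "g1.1", 2 + nchar(exon1) + 34,
                      2 + nchar(exon1) + 34 + nchar(exon2)))
  build1 <- function(genome, protein = NULL) {
    pr <- if (is.null(protein)) NULL else
      Biostrings::AAStringSet(c(g1.1 = protein))
    isoforms(buildGeneModels(ann, genome, proteins = pr)[[1]])[[1]]
  }

  expect_equal(issues(build1(mkGene("GT", "AG"))), character(0))
  expect_equal(issues(build1(mkGene("GC", "AG"))), character(0))
  iso <- build1(mkGene("AT", "AC"))
  expect_true("noncanonical_intron" %in% issues(iso))
  expect_equal(completeness(iso), "incomplete")

  # missing terminal stop
  exon2nostop <- paste0(paste(rep("CTG", 12), collapse = ""), "GCA")
  iso <- build1(mkGene(exon2. = exon2nostop))
  expect_true("missing_stop" %in% issues(iso))

  # a single planted coding mutation trips exactly the protein cross-check
  protein <- paste0("M", paste(rep("A", 12), collapse = ""),
                    paste(rep("L", 12), collapse = ""))
  expect_equal(issues(build1(mkGene(), protein)), character(0))
  mutated <- sub("GCAGCA", "GCAGAA", paste0("CC", exon1))  # A -> E
  genomeMut <- makeGenome(paste0(mutated,
                                 paste0("GT", paste(rep("T", 30),
                                                    collapse = ""), "AG"),
                                 exon2, "CC"))
  iso <- build1(genomeMut, protein)
  expect_equal(issues(iso), "protein_mismatch")
})

test_that("minus-strand genes mirror their plus-strand counterparts", {
  spec <- plantSpec(nGenes = 1, exonsPerGene = c(3, 3),
                    exonAaLen = c(18, 25), intronLen = c(90, 140),
                    intergenicNt = 100, minusStrandProb = 0, seed = 77)
  g <- generatePlantedGenome(spec)
  L <- Biostrings::width(g$genome)[1]
  rcGenome <- Biostrings::DNAStringSet(
    c(chr1 = as.character(Biostrings::reverseComplement(g$genome[[1]]))))
  rcAnn <- g$annotation
  rcAnn$start <- L - g$annotation$end
  rcAnn$end <- L - g$annotation$start
  rcAnn$strand <- "-"
  ord <- order(-rcAnn$start)
  rcAnn <- rcAnn[ord, ]

  isoP <- isoforms(buildGeneModels(g$annotation, g$genome)[[1]])[[1]]
  isoM <- isoforms(buildGeneModels(rcAnn, rcGenome)[[1]])[[1]]
  expect_equal(exons(isoM)$peptide, exons(isoP)$peptide)
  expect_equal(exons(isoM)$startPhase, exons(isoP)$startPhase)
  expect_equal(exons(isoM)$ntLen, exons(isoP)$ntLen)
  expect_equal(completeness(isoM), "complete")
})

test_that("phase-chain invariant holds and junction-aware peptides concatenate to the CDS translation", {
  spec <- plantSpec(nGenes = 20, exonsPerGene = c(2, 5),
                    exonAaLen = c(15, 30), intronLen = c(80, 150),
                    intergenicNt = 120, minusStrandProb = 0.5, seed = 404)
  g <- generatePlantedGenome(spec)
  models <- buildGeneModels(g$annotation, g$genome)
  for (m in models) for (iso in isoforms(m)) {
    ex <- exons(iso)
    if (nrow(ex) > 1)
      for (i in seq_len(nrow(ex) - 1))
        expect_equal(ex$startPhase[i + 1],
                     (3 - (ex$ntLen[i] - ex$startPhase[i]) %% 3) %% 3)
    cds <- mxefinder:::.isoformCDS(ex, g$genome, iso@targetId, iso@strand)
    expect_equal(paste(ex$displayPeptide, collapse = ""),
                 oracleTranslate(cds, ex$startPhase[1]))
  }
})
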