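randPep <- function(n) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
           "F", "P", "S", "T", "W", "Y", "V")
  paste(sample(aas, n, TRUE), collapse = "")
}

test_that("similarity score is self-normalized and matches the DP oracle", {
  expect_identical(similarityScore("MKVLAT", "MKVLAT"), 100)
  # frozen value computed with the independent aligner:
  # align(MKVLAT, MRVLAT) = 24, self = 27
  expect_equal(similarityScore("MKVLAT", "MRVLAT"), 100 * 24 / 27)
  set.seed(42)
  for (k in 1:30) {
    a <- randPep(sample(5:40, 1))
    b <- randPep(sample(5:40, 1))
    expect_equal(similarityScore(a, b), oracleSimilarity(a, b),
                 tolerance = 1e-12)
  }
  expect_error(similarityScore("", "MKV"), "empty")
  expect_error(similarityScore("MKV", ""), "empty")
})

test_that("shuffled peptide pairs almost never reach the display threshold", {
  set.seed(99)
  n <- 100
  below <- 0
  for (k in seq_len(n)) {
    a <- randPep(30)
    b <- paste(sample(strsplit(a, "")[[1]]), collapse = "")
    if (similarityScore(a, b) < 15) below <- below + 1
  }
  expect_gte(below, 95)
})

test_that("frame compatibility is the mod-3 rule", {
  expect_true(frameCompatible(60, 63))
  expect_false(frameCompatible(60, 62))
  expect_true(frameCompatible(60, 60))
  expect_equal(frameCompatible(60, c(57, 58, 66)), c(TRUE, FALSE, TRUE))
})

srcRowFor <- function(nt, phase = 0L, start = -1000, isTerminal = FALSE) {
  data.frame(start = start, end = start + nchar(nt), ntLen = nchar(nt),
             startPhase = phase, aaLen = nchar(nt) %/% 3L,
             peptide = exonPeptide(nt, phase), isTerminal = isTerminal,
             stringsAsFactors = FALSE)
}

test_that("a region without an AG acceptor yields no candidate", {
  region <- paste(rep("GTTT", 60), collapse = "")
  src <- srcRowFor(paste(rep("GCA", 20), collapse = ""))
  out <- enumerateCandidates(region, 0, nchar(region), "+", src,
                             predictionParams())
  expect_equal(nrow(out), 0)
})

test_that("an exact planted copy is recovered with score 100 and zero length difference", {
  set.seed(7)
  srcNt <- mxefinder:::.backTranslate(randPep(20))
  src <- srcRowFor(srcNt)
  region <- randomIntronWithPlant(400, plantNt = srcNt, margin = 60)
  out <- enumerateCandidates(region, 0, nchar(region), "+", src,
                             predictionParams())
  out <- resolveOverlappingCandidates(out)
  hit <- out[out$score == 100, ]
  expect_equal(nrow(hit), 1)
  expect_equal(hit$lenDiffAa, 0L)
  expect_equal(substr(region, hit$start - 1, hit$start), "AG")
  expect_true(substr(region, hit$end + 1, hit$end + 2) %in% c("GT", "GC"))
})

test_that("enumeration equals a literal brute force on random introns", {
  set.seed(11)
  p <- predictionParams("store")
  for (k in 1:6) {
    srcNt <- mxefinder:::.backTranslate(randPep(sample(12:20, 1)))
    src <- srcRowFor(srcNt, phase = sample(0:2, 1))
    plant <- if (k %% 2 == 0)
      mxefinder:::.altExonFromSource(srcNt, src$startPhase, 0.8, 0)$nt else NULL
    region <- randomIntronWithPlant(700, plantNt = plant, margin = 50)
    mine <- enumerateCandidates(region, 0, nchar(region), "+", src, p)
    ref <- oracleEnumerate(region, src$ntLen, src$startPhase, src$peptide,
                           FALSE, p@minScore, p@maxLenDiff,
                           p@minCandidateMargin)
    expect_setequal(paste(mine$start, mine$end), paste(ref$start, ref$end))
  }
})

test_that("overlap resolution keeps the best candidate and all disjoint ones", {
  two <- data.frame(start = c(10, 100), end = c(40, 130),
                    score = c(50, 20), lenDiffAa = c(0L, 0L))
  expect_equal(nrow(resolveOverlappingCandidates(two)), 2)
  over <- data.frame(start = c(10, 20), end = c(40, 50),
                     score = c(80, 40), lenDiffAa = c(0L, 0L))
  expect_equal(resolveOverlappingCandidates(over)$score, 80)

  # random sets against an independent greedy re-implementation
  set.seed(21)
  for (k in 1:20) {
    n <- sample(3:12, 1)
    s <- sample(1:200, n)
    df <- data.frame(start = s, end = s + sample(10:60, n, TRUE),
                     score = round(runif(n, 0, 100), 1),
                     lenDiffAa = sample(0:5, n, TRUE))
    ref <- local({
      ord <- order(-df$score, df$lenDiffAa, df$start)
      kept <- list()
      for (i in ord) {
        clash <- any(vapply(kept, function(r)
          df$start[i] < r[2] && r[1] < df$end[i], logical(1)))
        if (!clash) kept[[length(kept) + 1]] <- c(df$start[i], df$end[i])
      }
      sort(vapply(kept, function(r) paste(r, collapse = "-"), character(1)))
    })
    mine <- resolveOverlappingCandidates(df)
    expect_equal(sort(paste(mine$start, mine$end, sep = "-")), ref)
  }
})

test_that("a single-exon gene without flank search yields no candidates", {
  cds <- paste0("ATG", paste(rep("GCA", 30), collapse = ""), "TAA")
  g <- Biostrings::DNAStringSet(c(chr1 = paste0("CCCC", cds, "GGGG")))
  ann <- data.frame(geneId = "g1", proteinId = "g1.1", targetId = "chr1",
                    start = 4, end = 4 + nchar(cds), strand = "+",
                    phase = 0L, stringsAsFactors = FALSE)
  m <- buildGeneModels(ann, g)[[1]]
  expect_equal(nrow(predictGene(m, g, predictionParams())), 0)
})

test_that("the worked-example gene yields 2a, 2c and 2d at the store stage", {
  fx <- fig2bFixture()
  m <- buildGeneModels(fx$annotation, fx$genome)[[1]]
  cands <- predictGene(m, fx$genome, predictionParams("store"))
  expect_equal(nrow(cands), 3)
  expect_setequal(paste(cands$start, cands$end),
                  paste(fx$expected$start, fx$expected$end))
  expect_equal(sort(unique(cands$location)),
               c("downstream_intron", "upstream_intron"))
})

test_that("searching all introns yields a superset of the flanking scope", {
  spec <- plantSpec(nGenes = 4, exonsPerGene = c(4, 4),
                    plants = data.frame(gene = 1:2, exon = 2, nAlt = 1,
                                        identity = 0.85, lenOffset = 0,
                                        side = "downstream"),
                    seed = 55)
  g <- generatePlantedGenome(spec)
  models <- buildGeneModels(g$annotation, g$genome)
  pFlank <- predictionParams(scope = "flanking")
  pAll <- predictionParams(scope = "all")
  for (m in models) {
    cf <- predictGene(m, g$genome, pFlank)
    ca <- predictGene(m, g$genome, pAll)
    expect_true(all(cf$candidateId %in% ca$candidateId))
  }
})

test_that("prediction is deterministic and scores are self-consistent", {
  fx <- fig2bFixture()
  m <- buildGeneModels(fx$annotation, fx$genome)[[1]]
  p <- predictionParams("store")
  c1 <- predictGene(m, fx$genome, p)
  c2 <- predictGene(m, fx$genome, p)
  expect_identical(c1, c2)
  ex <- exons(isoforms(m)[[1]])
  for (i in seq_len(nrow(c1))) {
    srcPep <- ex$peptide[ex$index == c1$sourceExonIndex[i]]
    expect_identical(similarityScore(srcPep, c1$peptide[i], p), c1$score[i])
  }
})

test_that("every intronic candidate is bounded by AG and GT/GC in the genome", {
  spec <- plantSpec(nGenes = 6,
                    plants = data.frame(gene = c(2, 5), exon = 2, nAlt = 2,
                                        identity = 0.8, lenOffset = 1,
                                        side = "both"),
                    minusStrandProb = 0.5, seed = 66)
  g <- generatePlantedGenome(spec)
  models <- buildGeneModels(g$annotation, g$genome)
  chr <- g$genome[[1]]
  for (m in models) {
    cands <- predictGene(m, g$genome, predictionParams())
    for (i in seq_len(nrow(cands))) {
      if (cands$strand[i] == "+") {
        acc <- as.character(Biostrings::subseq(chr, cands$start[i] - 1,
                                               cands$start[i]))
        don <- as.character(Biostrings::subseq(chr, cands$end[i] + 1,
                                               cands$end[i] + 2))
      } else {
        acc <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chr, cands$end[i] + 1, cands$end[i] + 2)))
        don <- as.character(Biostrings::reverseComplement(
          Biostrings::subseq(chr, cands$start[i] - 1, cands$start[i])))
      }
      expect_equal(acc, "AG")
      expect_true(don %in% c("GT", "GC"))
    }
  }
})

test_that("predictions mirror exactly on the reverse-complemented genome", {
  spec <- plantSpec(nGenes = 2, exonsPerGene = c(3, 3),
                    plants = data.frame(gene = 1, exon = 2, nAlt = 1,
                                        identity = 0.85, lenOffset = 0,
                                        side = "downstream"),
                    minusStrandProb = 0, seed = 88)
  g <- generatePlantedGenome(spec)
  L <- Biostrings::width(g$genome)[1]
  rcGenome <- Biostrings::DNAStringSet(
    c(chr1 = as.character(Biostrings::reverseComplement(g$genome[[1]]))))
  rcAnn <- g$annotation
  rcAnn$start <- L - g$annotation$end
  rcAnn$end <- L - g$annotation$start
  rcAnn$strand <- "-"
  rcAnn <- rcAnn[order(rcAnn$geneId, rcAnn$proteinId, -rcAnn$start), ]

  p <- predictionParams()
  fwd <- do.call(rbind, lapply(buildGeneModels(g$annotation, g$genome),
                               predictGene, g$genome, p))
  rev <- do.call(rbind, lapply(buildGeneModels(rcAnn, rcGenome),
                               predictGene, rcGenome, p))
  expect_equal(nrow(rev), nrow(fwd))
  fwdKey <- sort(paste(fwd$geneId, fwd$sourceExonIndex, fwd$location,
                       L - fwd$end, L - fwd$start, round(fwd$score, 9)))
  revKey <- sort(paste(rev$geneId, rev$sourceExonIndex, rev$location,
                       rev$start, rev$end, round(rev$score, 9)))
  expect_equal(revKey, fwdKey)
})

test_that("relaxing thresholds never removes a candidate", {
  fx <- fig2bFixture()
  m <- buildGeneModels(fx$annotation, fx$genome)[[1]]
  strict <- predictGene(m, fx$genome, predictionParams())
  relaxed <- predictGene(m, fx$genome, predictionParams("store"))
  expect_true(all(strict$candidateId %in% relaxed$candidateId))
})
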