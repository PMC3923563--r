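fig2bStore <- function() {
  fx <- fig2bFixture()
  m <- buildGeneModels(fx$annotation, fx$genome)[[1]]
  cands <- predictGene(m, fx$genome, predictionParams("store"))
  list(fx = fx, model = m, cands = cands)
}

candName <- function(cands, fx) {
  fx$expected$name[match(paste(cands$start, cands$end),
                         paste(fx$expected$start, fx$expected$end))]
}

test_that("the display filters act on the worked example exactly as documented", {
  st <- fig2bStore()
  # default display values remove exactly the low-scoring 2c
  f <- applyFilters(st$cands, predictionParams())
  expect_setequal(candName(f$candidates, st$fx), c("2a", "2d"))
  rep2c <- f$report[!f$report$pass, ]
  expect_equal(nrow(rep2c), 1)
  expect_equal(rep2c$firstFail, "score")

  # tightening only the length bound below 12 aa removes exactly 2a and 2d
  f <- applyFilters(st$cands, predictionParams("store", maxLenDiff = 11))
  expect_setequal(candName(f$candidates, st$fx), "2c")
  expect_equal(sort(f$report$firstFail[!f$report$pass]),
               c("length_diff", "length_diff"))

  # a minimum original exon length above 18 aa removes every candidate
  f <- applyFilters(st$cands, predictionParams("store", minExonLen = 19))
  expect_equal(nrow(f$candidates), 0)
  expect_equal(unique(f$report$firstFail), "min_exon_len")
})

test_that("filtering is pure: idempotent and invariant to candidate order", {
  st <- fig2bStore()
  p <- predictionParams()
  once <- applyFilters(st$cands, p)$candidates
  twice <- applyFilters(once, p)$candidates
  expect_identical(twice, once)

  shuffled <- st$cands[rev(seq_len(nrow(st$cands))), ]
  f2 <- applyFilters(shuffled, p)$candidates
  expect_setequal(f2$candidateId, once$candidateId)
})

test_that("every candidate appears exactly once in the filter report", {
  st <- fig2bStore()
  f <- applyFilters(st$cands, predictionParams())
  expect_setequal(f$report$candidateId, st$cands$candidateId)
  expect_equal(anyDuplicated(f$report$candidateId), 0)
})

test_that("isoform reconciliation flags exact matches, overlaps and neighbours", {
  isoA <- makeIso("A", c(100, 300, 600), c(160, 360, 690))
  isoB <- makeIso("B", c(100, 430, 600), c(160, 490, 690))
  nb <- data.frame(geneId = "gNext", start = 2000, end = 2100,
                   stringsAsFactors = FALSE)
  gene <- makeGene("g1", list(isoA, isoB), neighbourExons = nb)

  # candidate equal to B's cassette exon: exact match, no overlap flag
  cand <- candRows("g1", "A", 2, 300, 360, start = 430, end = 490)
  r <- reconcileIsoforms(gene, cand)
  expect_true(r$flagExactMatch)
  expect_false(r$flagIsoformOverlap)

  # shifted by 3 nt: overlap flag only
  cand <- candRows("g1", "A", 2, 300, 360, start = 433, end = 493)
  r <- reconcileIsoforms(gene, cand)
  expect_false(r$flagExactMatch)
  expect_true(r$flagIsoformOverlap)

  # overlapping a neighbouring gene's exon
  cand <- candRows("g1", "A", 2, 300, 360, start = 1990, end = 2050,
                   location = "downstream_flank")
  r <- reconcileIsoforms(gene, cand)
  expect_true(r$flagNeighbourOverlap)

  # single isoform, no neighbours: all flags stay FALSE
  g1 <- makeGene("g2", list(isoA))
  r <- reconcileIsoforms(g1, candRows("g2", "A", 2, 300, 360, 430, 490))
  expect_false(any(r$flagExactMatch, r$flagIsoformOverlap,
                   r$flagNeighbourOverlap))
})

test_that("overlap-but-not-exact candidates are deselected only by the overlap filter", {
  cand <- candRows("g1", "A", 2, 300, 360, start = c(430, 500),
                   end = c(490, 560), score = c(60, 60))
  cand$flagIsoformOverlap <- c(TRUE, FALSE)
  p <- predictionParams("store")
  f <- applyFilters(cand, p)
  expect_equal(f$report$firstFail[!f$report$pass], "overlap")
  expect_equal(nrow(f$candidates), 1)
  pKeep <- predictionParams("store", excludeIsoformOverlaps = FALSE)
  expect_equal(nrow(applyFilters(cand, pKeep)$candidates), 2)
  # an exact match is confirmation, never removed
  cand$flagExactMatch <- c(TRUE, FALSE)
  expect_equal(nrow(applyFilters(cand, p)$candidates), 2)
})

test_that("annotated-MXE clusters require exactly one member per isoform", {
  # swapped middle exons: one cluster {2a, 2b}
  isoA <- makeIso("A", c(100, 300, 600), c(160, 360, 690))
  isoB <- makeIso("B", c(100, 430, 600), c(160, 490, 690))
  cls <- detectAnnotatedMXEClusters(makeGene("g", list(isoA, isoB)))
  expect_length(cls, 1)
  expect_equal(members(cls[[1]])$start, c(300, 430))
  expect_equal(clusterType(cls[[1]]), "internal")

  # cassette pattern: isoform B contains both members, no cluster
  isoB2 <- makeIso("B", c(100, 300, 430, 600), c(160, 360, 490, 690))
  expect_length(detectAnnotatedMXEClusters(makeGene("g", list(isoA, isoB2))),
                0)

  # single isoform: none
  expect_length(detectAnnotatedMXEClusters(makeGene("g", list(isoA))), 0)

  # an isoform skipping the cluster entirely disqualifies it
  isoC <- makeIso("C", c(100, 600), c(160, 690))
  expect_length(
    detectAnnotatedMXEClusters(makeGene("g", list(isoA, isoB, isoC))), 0)
})

test_that("generator annotated-MXE pattern is detected from the annotation alone", {
  spec <- plantSpec(nGenes = 3, isoformPattern = c("annotated_mxe", "single",
                                                   "cassette"), seed = 91)
  g <- generatePlantedGenome(spec)
  models <- buildGeneModels(g$annotation, g$genome)
  cls <- lapply(models, detectAnnotatedMXEClusters)
  expect_length(cls[["gene001"]], 1)
  expect_equal(nrow(members(cls[["gene001"]][[1]])), 2)
  expect_length(cls[["gene002"]], 0)
  expect_length(cls[["gene003"]], 0)   # cassette isoform disqualifies
})

test_that("constitutive neighbours matching the MXE criteria are flagged", {
  pepX <- strrep("K", 20)
  # identical adjacent exons: flagged with score 100
  iso <- makeIso("A", c(100, 300, 500), c(160, 360, 560),
                 peptides = c(pepX, pepX, strrep("D", 20)))
  out <- detectConstitutiveMXELike(makeGene("g", list(iso)),
                                   predictionParams())
  expect_equal(nrow(out), 1)
  expect_equal(out$score, 100)
  expect_equal(out$exonIndexA, 1L)

  # frame-incompatible neighbours are never flagged
  iso2 <- makeIso("A", c(100, 300), c(160, 361), peptides = c(pepX, pepX))
  expect_equal(nrow(detectConstitutiveMXELike(makeGene("g", list(iso2)),
                                              predictionParams())), 0)

  # duplicated neighbouring exon block at ~70% identity (myosin-like)
  set.seed(31)
  srcNt <- mxefinder:::.backTranslate(paste(sample(
    c("A","R","N","D","C","Q","E","G","H","I","L","K","M","F","P","S","T",
      "W","Y","V"), 25, TRUE), collapse = ""))
  dupNt <- mxefinder:::.altExonFromSource(srcNt, 0L, 0.7, 0)$nt
  iso3 <- makeIso("A", c(100, 300), c(100 + nchar(srcNt), 300 + nchar(dupNt)),
                  peptides = c(exonPeptide(srcNt, 0L), exonPeptide(dupNt, 0L)))
  out3 <- detectConstitutiveMXELike(makeGene("g", list(iso3)),
                                    predictionParams())
  expect_equal(nrow(out3), 1)
  expect_gte(out3$score, 15)
})

test_that("cluster assembly groups each source exon with its candidates and merges", {
  # one source exon with two disjoint candidates: one 3-member cluster
  gene <- makeGene("g", list(makeIso("A", c(100, 300, 600),
                                     c(160, 360, 690))))
  surv <- candRows("g", "A", 2, 300, 360, start = c(430, 500),
                   end = c(490, 560), score = c(60, 40))
  cls <- assembleClusters(gene, surv)
  expect_length(cls, 1)
  expect_equal(nrow(members(cls[[1]])), 3)
  expect_equal(members(cls[[1]])$provenance,
               c("annotated_exon", "predicted_new", "predicted_new"))

  # the worked example assembles one internal cluster of four
  st <- fig2bStore()
  cls <- assembleClusters(st$model, st$cands)
  expect_length(cls, 1)
  expect_equal(nrow(members(cls[[1]])), 4)
  expect_equal(clusterType(cls[[1]]), "internal")

  # mutual prediction: two sources predicting each other merge into one
  gene2 <- makeGene("g", list(makeIso("A", c(100, 300, 430, 600),
                                      c(160, 360, 490, 690))))
  surv2 <- rbind(
    candRows("g", "A", 2, 300, 360, start = 430, end = 490),
    candRows("g", "A", 3, 430, 490, start = 300, end = 360,
             location = "upstream_intron"))
  cls2 <- assembleClusters(gene2, surv2)
  expect_length(cls2, 1)
  expect_equal(members(cls2[[1]])$start, c(300, 430))
})

test_that("cross-isoform mutual prediction merges into a single two-member cluster", {
  spec <- plantSpec(nGenes = 1, isoformPattern = "annotated_mxe", seed = 17)
  g <- generatePlantedGenome(spec)
  m <- buildGeneModels(g$annotation, g$genome)[[1]]
  cands <- reconcileIsoforms(m, predictGene(m, g$genome, predictionParams()))
  surv <- applyFilters(cands, predictionParams())$candidates
  cls <- assembleClusters(m, surv)
  expect_length(cls, 1)
  expect_equal(nrow(members(cls[[1]])), 2)
  expect_true(all(members(cls[[1]])$provenance == "annotated_exon"))
})

test_that("clusters classify by the terminal exons they contain", {
  gene <- makeGene("g", list(makeIso("A", c(100, 300, 600),
                                     c(160, 360, 690))))
  clusterAt <- function(starts, ends) {
    new("MXECluster", clusterId = "t", geneId = "g", targetId = "chr1",
        strand = "+", type = "internal",
        members = data.frame(start = starts, end = ends,
                             provenance = "annotated_exon",
                             sourceExonIndex = NA_integer_,
                             score = NA_real_, stringsAsFactors = FALSE))
  }
  expect_equal(classifyCluster(clusterAt(c(30, 100), c(90, 160)), gene),
               "initial")
  expect_equal(classifyCluster(clusterAt(c(600, 800), c(690, 890)), gene),
               "terminal")
  expect_equal(classifyCluster(clusterAt(c(300, 430), c(360, 490)), gene),
               "internal")
  # two-exon isoform: first and last exon in one cluster -> initial wins
  gene2 <- makeGene("g2", list(makeIso("A", c(100, 300), c(160, 360))))
  expect_message(
    ty <- classifyCluster(clusterAt(c(100, 300), c(160, 360)), gene2),
    "both initial and terminal")
  expect_equal(ty, "initial")
})

test_that("ordered flank copies of several exons raise the tandem/trans flag", {
  gene <- makeGene("g", list(makeIso("A", c(100, 300, 600),
                                     c(160, 360, 690))))
  none <- candRows("g", "A", 2, 300, 360, 430, 490)
  expect_false(flagTandemOrTrans(gene, none)$flag)

  ordered <- rbind(
    candRows("g", "A", 2, 300, 360, start = 800, end = 860,
             location = "downstream_flank"),
    candRows("g", "A", 3, 600, 690, start = 900, end = 990,
             location = "downstream_flank"))
  r <- flagTandemOrTrans(gene, ordered)
  expect_true(r$flag)
  expect_equal(nrow(r$supporting), 2)

  inverted <- rbind(
    candRows("g", "A", 3, 600, 690, start = 800, end = 890,
             location = "downstream_flank"),
    candRows("g", "A", 2, 300, 360, start = 900, end = 960,
             location = "downstream_flank"))
  expect_false(flagTandemOrTrans(gene, inverted)$flag)
})

test_that("a duplicated gene tail is flagged through the real flank search", {
  spec <- plantSpec(nGenes = 1, exonsPerGene = c(4, 4), flankDup = TRUE,
                    minusStrandProb = 0, seed = 23)
  g <- generatePlantedGenome(spec)
  m <- buildGeneModels(g$annotation, g$genome)[[1]]
  cands <- predictGene(m, g$genome, predictionParams("store"))
  r <- flagTandemOrTrans(m, cands)
  expect_true(r$flag)
  expect_setequal(unique(r$supporting$sourceExonIndex), c(2L, 3L))
})
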