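# Deterministic synthetic genomes with planted MXE clusters, decoy-free
# introns, multi-isoform annotation patterns and a worked three-exon example
# gene whose planted alternatives exercise every display filter.

.codonTable <- function() {
  if (is.null(.mxeCache$codons)) {
    gc <- GENETIC_CODE
    .mxeCache$codons <- split(names(gc), unname(gc))
  }
  .mxeCache$codons
}

.aaLetters <- function() setdiff(names(.codonTable()), "*")

.randPeptide <- function(n, first = NULL) {
  aa <- sample(.aaLetters(), n, replace = TRUE)
  if (!is.null(first) && n > 0) aa[1] <- first
  paste(aa, collapse = "")
}

# back-translate; deterministic = first codon of each amino acid,
# otherwise a uniformly random synonymous codon
.backTranslate <- function(pep, deterministic = FALSE) {
  tab <- .codonTable()
  aas <- strsplit(pep, "")[[1]]
  codons <- vapply(aas, function(a) {
    cs <- sort(tab[[a]])
    if (deterministic) cs[1] else sample(cs, 1)
  }, character(1), USE.NAMES = FALSE)
  paste(codons, collapse = "")
}

.randNt <- function(n) paste(sample(c("A", "C", "G", "T"), n, replace = TRUE),
                             collapse = "")

# uniform draw from an inclusive integer range (safe for degenerate ranges,
# unlike sample(x, ...) on a scalar x)
.sampleRange <- function(lo, hi, n = 1L) {
  if (lo >= hi) return(rep(as.integer(lo), n))
  as.integer(sample(seq.int(lo, hi), n, replace = TRUE))
}

# mutate a peptide to a target amino-acid identity (exact substitution count)
.mutatePeptide <- function(pep, identity) {
  aas <- strsplit(pep, "")[[1]]
  m <- length(aas)
  nSub <- round(m * (1 - identity))
  if (nSub > 0) {
    pos <- sample.int(m, nSub)
    for (p in pos) aas[p] <- sample(setdiff(.aaLetters(), aas[p]), 1)
  }
  list(pep = paste(aas, collapse = ""), nSub = nSub,
       realizedIdentity = (m - nSub) / m)
}

# build an alternative-exon nucleotide sequence from a source exon: the
# partial codons at the edges are kept verbatim (frame preservation by
# construction), the complete-codon region is mutated at the amino-acid
# level and whole codons are inserted/deleted in the middle
.altExonFromSource <- function(exonNt, startPhase, identity, lenOffsetCodons,
                               keepStop = FALSE) {
  n <- nchar(exonNt)
  prefix <- substr(exonNt, 1L, startPhase)
  m <- (n - startPhase) %/% 3L
  codonRegion <- substr(exonNt, startPhase + 1L, startPhase + 3L * m)
  suffix <- substr(exonNt, startPhase + 3L * m + 1L, n)
  pep <- .translateCodons(codonRegion)
  stopPart <- ""
  if (keepStop && substr(pep, nchar(pep), nchar(pep)) == "*") {
    stopPart <- substr(codonRegion, 3L * m - 2L, 3L * m)
    codonRegion <- substr(codonRegion, 1L, 3L * (m - 1L))
    pep <- substr(pep, 1L, nchar(pep) - 1L)
    m <- m - 1L
  }
  mut <- .mutatePeptide(pep, identity)
  aas <- strsplit(mut$pep, "")[[1]]
  origCodons <- substring(codonRegion, 3L * seq_len(m) - 2L, 3L * seq_len(m))
  origAas <- strsplit(pep, "")[[1]]
  codons <- ifelse(aas == origAas, origCodons,
                   vapply(aas, function(a) sample(sort(.codonTable()[[a]]), 1),
                          character(1), USE.NAMES = FALSE))
  mid <- m %/% 2L
  if (lenOffsetCodons > 0) {
    ins <- vapply(sample(.aaLetters(), lenOffsetCodons, replace = TRUE),
                  function(a) sample(sort(.codonTable()[[a]]), 1),
                  character(1), USE.NAMES = FALSE)
    codons <- append(codons, ins, after = mid)
  } else if (lenOffsetCodons < 0) {
    k <- -lenOffsetCodons
    if (k >= m) stop("length offset deletes the whole exon")
    del <- seq(mid + 1L, mid + k)
    del <- del[del <= m]
    codons <- codons[-del]
  }
  list(nt = paste0(prefix, paste(codons, collapse = ""), stopPart, suffix),
       realizedIdentity = mut$realizedIdentity)
}

#' Create a synthetic-genome specification
#'
#' The defaults describe a compact but realistic exome: genes of 3--5 coding
#' exons of 20--40 amino acids separated by 200--500 nt canonical GT...AG
#' introns, 800 nt intergenic spacers, and no planted clusters.  All
#' randomness is governed by \code{seed}; the same seed yields byte-identical
#' output.
#'
#' @param nGenes number of genes.
#' @param exonsPerGene,exonAaLen,intronLen inclusive ranges (length-2
#'   integer vectors).
#' @param intergenicNt intergenic spacer length.
#' @param plants data.frame of planted alternatives (columns \code{gene},
#'   \code{exon}, \code{nAlt}, \code{identity}, \code{lenOffset},
#'   \code{side}); NULL for none.  See [PlantSpec-class].
#' @param isoformPattern per-gene pattern (\code{"single"},
#'   \code{"annotated_mxe"}, \code{"cassette"}); recycled to \code{nGenes}.
#' @param patternIdentity amino-acid identity of the pattern alternative
#'   exon; recycled to \code{nGenes}.
#' @param gcDonorProb probability of a GC donor for a plain intron.
#' @param flankDup plant ordered downstream copies of exons 2 and 3.
#' @param minusStrandProb probability a gene lies on the minus strand.
#' @param seed integer seed.
#' @return a [PlantSpec-class].
#' @export
plantSpec <- function(nGenes = 10, exonsPerGene = c(3, 5),
                      exonAaLen = c(20, 40), intronLen = c(200, 500),
                      intergenicNt = 800, plants = NULL,
                      isoformPattern = "single", patternIdentity = 0.85,
                      gcDonorProb = 0, flankDup = FALSE,
                      minusStrandProb = 0.3, seed = 1) {
  if (is.null(plants))
    plants <- data.frame(gene = integer(0), exon = integer(0),
                         nAlt = integer(0), identity = numeric(0),
                         lenOffset = integer(0), side = character(0),
                         stringsAsFactors = FALSE)
  new("PlantSpec", nGenes = as.integer(nGenes),
      exonsPerGene = as.integer(exonsPerGene),
      exonAaLen = as.integer(exonAaLen), intronLen = as.integer(intronLen),
      intergenicNt = as.integer(intergenicNt), plants = plants,
      isoformPattern = rep_len(as.character(isoformPattern), nGenes),
      patternIdentity = rep_len(as.numeric(patternIdentity), nGenes),
      gcDonorProb = gcDonorProb, flankDup = flankDup,
      minusStrandProb = minusStrandProb, seed = as.integer(seed))
}

# parameters used to screen generated introns for chance (decoy) candidates:
# the relaxed store values, so anything the pipeline could ever pick up is
# rejected at generation time
.screenParams <- function() predictionParams("store")

# enumerate an intron against one flanking exon (local coordinates) and
# resolve overlaps, mirroring what the prediction pipeline reports
.screenIntron <- function(intronSeq, intronStart, exonRow, params) {
  f <- enumerateCandidates(intronSeq, intronStart,
                           intronStart + nchar(intronSeq), "+", exonRow,
                           params)
  resolveOverlappingCandidates(f)
}

# assemble one intron (local coding orientation), planting the given
# alternative sequences; returns sequence plus local (intron-relative)
# planted intervals
.assembleIntron <- function(targetLen, altSeqs, donor = "GT") {
  k <- length(altSeqs)
  minPad <- 25L
  need <- 2L + 2L + (if (k) sum(nchar(altSeqs)) + 4L * k else 0L) +
    (k + 1L) * minPad
  tot <- max(targetLen, need)
  extra <- tot - need
  padLens <- rep(minPad, k + 1L)
  if (extra > 0) {
    add <- stats::rmultinom(1, extra, rep(1, k + 1L))[, 1]
    padLens <- padLens + add
  }
  parts <- donor
  plantLocal <- matrix(numeric(0), ncol = 2)
  pos <- 2L + padLens[1L]
  parts <- c(parts, .randNt(padLens[1L]))
  if (k) {
    for (j in seq_len(k)) {
      parts <- c(parts, "AG", altSeqs[j], "GT")
      plantLocal <- rbind(plantLocal, c(pos + 2L, pos + 2L + nchar(altSeqs[j])))
      pos <- pos + 2L + nchar(altSeqs[j]) + 2L + padLens[j + 1L]
      parts <- c(parts, .randNt(padLens[j + 1L]))
    }
  }
  parts <- c(parts, "AG")
  list(seq = paste(parts, collapse = ""), plantLocal = plantLocal)
}

# build one gene in local coding-strand coordinates
.buildLocalGene <- function(spec, geneIdx) {
  nEx <- .sampleRange(spec@exonsPerGene[1], spec@exonsPerGene[2])
  pattern <- spec@isoformPattern[geneIdx]
  plants <- spec@plants[spec@plants$gene == geneIdx, , drop = FALSE]
  if (pattern != "single" && nEx < 3) nEx <- 3L
  if (nrow(plants) && any(plants$exon <= 1 | plants$exon >= nEx))
    stop("planted cluster source exon must be internal (gene ", geneIdx, ")")

  aaLens <- .sampleRange(spec@exonAaLen[1], spec@exonAaLen[2], nEx)
  pep <- .randPeptide(sum(aaLens), first = "M")
  cds <- paste0(.backTranslate(pep), "TAA")

  # exon boundaries within the CDS; codon-aligned at exons that seed plants
  # or annotation patterns, random phase offsets elsewhere
  alignedExons <- unique(c(plants$exon, if (pattern != "single") 2L))
  bounds <- 3L * cumsum(aaLens)
  d <- integer(nEx - 1L)
  for (i in seq_len(nEx - 1L)) {
    aligned <- (i %in% alignedExons) || ((i + 1L) %in% alignedExons)
    d[i] <- if (aligned) 0L else sample(0:2, 1)
  }
  cuts <- c(0L, bounds[-nEx] + d, nchar(cds))
  exonNt <- substring(cds, cuts[-length(cuts)] + 1L, cuts[-1L])
  phases <- integer(nEx)
  for (i in seq_len(nEx)[-1])
    phases[i] <- .nextPhase(nchar(exonNt[i - 1L]), phases[i - 1L])

  # alternatives to plant, per junction (junction i = intron after exon i)
  junctionAlts <- vector("list", nEx - 1L)
  truth <- list()
  addAlt <- function(junction, srcExon, identity, lenOffset, role) {
    alt <- .altExonFromSource(exonNt[srcExon], phases[srcExon], identity,
                              lenOffset)
    junctionAlts[[junction]] <<- c(junctionAlts[[junction]],
                                   stats::setNames(list(alt$nt),
                                                   length(truth) + 1L))
    truth[[length(truth) + 1L]] <<- list(
      junction = junction, sourceExon = srcExon,
      targetIdentity = identity,
      realizedIdentity = alt$realizedIdentity,
      lenOffset = lenOffset, role = role, nt = alt$nt)
  }
  for (r in seq_len(nrow(plants))) {
    sides <- switch(plants$side[r], upstream = "upstream",
                    downstream = "downstream",
                    both = c("upstream", "downstream"),
                    stop("unknown plant side: ", plants$side[r]))
    nAlt <- plants$nAlt[r]
    for (a in seq_len(nAlt)) {
      side <- sides[1L + (a - 1L) %% length(sides)]
      junction <- if (side == "upstream") plants$exon[r] - 1L else
        plants$exon[r]
      addAlt(junction, plants$exon[r], plants$identity[r],
             plants$lenOffset[r], "plant")
    }
  }
  if (pattern != "single")
    addAlt(2L, 2L, spec@patternIdentity[geneIdx], 0L, "pattern")

  # assemble introns, screening each against its flanking exons and
  # resampling the random padding until no chance candidate survives
  screen <- .screenParams()
  intronSeq <- character(nEx - 1L)
  intronPlantLocal <- vector("list", nEx - 1L)
  exonRowFor <- function(i, startLocal) {
    data.frame(start = startLocal, end = startLocal + nchar(exonNt[i]),
               ntLen = nchar(exonNt[i]), startPhase = phases[i],
               aaLen = nchar(exonNt[i]) %/% 3L,
               peptide = exonPeptide(exonNt[i], phases[i]),
               isTerminal = i == nEx, stringsAsFactors = FALSE)
  }
  for (j in seq_len(nEx - 1L)) {
    alts <- unlist(junctionAlts[[j]], use.names = FALSE)
    if (is.null(alts)) alts <- character(0)
    targetLen <- .sampleRange(spec@intronLen[1], spec@intronLen[2])
    minNeed <- 4L + (if (length(alts)) sum(nchar(alts)) + 4L * length(alts)
                     else 0L) + 25L * (length(alts) + 1L)
    if (length(alts) && spec@intronLen[2] < minNeed)
      stop("infeasible spec: intron length range [", spec@intronLen[1], ",",
           spec@intronLen[2], "] too short for planted candidates plus ",
           "margins (need >= ", minNeed, " nt) at gene ", geneIdx)
    donor <- if (stats::runif(1) < spec@gcDonorProb) "GC" else "GT"
    jt <- which(vapply(truth, function(t) t$junction == j, logical(1)))
    ok <- FALSE
    asm <- NULL
    for (try in seq_len(80)) {
      asm <- .assembleIntron(targetLen, alts, donor = donor)
      # local frame: the intron region spans [0, n); flanking exons adjacent
      leftRow <- exonRowFor(j, -nchar(exonNt[j]))
      rightRow <- exonRowFor(j + 1L, nchar(asm$seq))
      f1 <- .screenIntron(asm$seq, 0, leftRow, screen)
      f2 <- .screenIntron(asm$seq, 0, rightRow, screen)
      plantedKeys <- if (nrow(asm$plantLocal))
        paste(asm$plantLocal[, 1], asm$plantLocal[, 2]) else character(0)
      foundKeys <- unique(c(paste(f1$start, f1$end),
                            paste(f2$start, f2$end)))
      ok <- all(foundKeys %in% plantedKeys)
      if (ok && length(jt)) {
        # every plant whose similarity clears the screen threshold must be
        # recoverable from its own source exon (heavily degraded plants are
        # legitimately invisible to the search)
        for (k in seq_along(jt)) {
          src <- truth[[jt[k]]]$sourceExon
          altPep <- exonPeptide(truth[[jt[k]]]$nt, phases[src])
          srcPep <- exonPeptide(exonNt[src], phases[src])
          if (similarityScore(srcPep, altPep, screen) < screen@minScore + 2)
            next
          sf <- if (src == j) f1 else f2
          if (!plantedKeys[k] %in% paste(sf$start, sf$end)) {
            ok <- FALSE
            break
          }
        }
      }
      if (ok) break
    }
    if (!ok)
      stop("could not assemble a decoy-free intron at gene ", geneIdx,
           ", junction ", j)
    intronSeq[j] <- asm$seq
    intronPlantLocal[[j]] <- asm$plantLocal
  }

  # local layout: exon1 intron1 exon2 ... ; then optional flank duplication
  segs <- character(0)
  exonStart <- numeric(nEx)
  intronStart <- numeric(max(0L, nEx - 1L))
  pos <- 0L
  for (i in seq_len(nEx)) {
    exonStart[i] <- pos
    segs <- c(segs, exonNt[i])
    pos <- pos + nchar(exonNt[i])
    if (i < nEx) {
      intronStart[i] <- pos
      segs <- c(segs, intronSeq[i])
      pos <- pos + nchar(intronSeq[i])
    }
  }
  geneEnd <- pos
  flankCopies <- list()
  if (spec@flankDup && nEx >= 3) {
    for (ci in c(2L, 3L)) {
      pad <- .randNt(80L + 10L * ci)
      segs <- c(segs, pad, "AG", exonNt[ci], "GT")
      pos <- pos + nchar(pad)
      flankCopies[[length(flankCopies) + 1L]] <-
        list(sourceExon = ci, start = pos + 2L,
             end = pos + 2L + nchar(exonNt[ci]))
      pos <- pos + 2L + nchar(exonNt[ci]) + 2L
    }
    tail <- .randNt(40L)
    segs <- c(segs, tail)
    pos <- pos + nchar(tail)
  }

  # resolve planted intervals to local gene coordinates; plants within a
  # junction appear in the same order in truth and in the intron layout
  truthLocal <- truth
  for (j in seq_len(max(0L, nEx - 1L))) {
    jt <- which(vapply(truth, function(t) t$junction == j, logical(1)))
    pl <- intronPlantLocal[[j]]
    for (k in seq_along(jt)) {
      truthLocal[[jt[k]]]$start <- intronStart[j] + pl[k, 1]
      truthLocal[[jt[k]]]$end <- intronStart[j] + pl[k, 2]
    }
  }

  list(nEx = nEx, exonNt = exonNt, phases = phases, exonStart = exonStart,
       exonEnd = exonStart + nchar(exonNt), length = pos,
       geneEnd = geneEnd, pattern = pattern, truth = truthLocal,
       flankCopies = flankCopies, pep = pep,
       seq = paste(segs, collapse = ""))
}

#' Generate a synthetic genome with planted MXE clusters
#'
#' Builds a deterministic genome (one contig) of protein-coding genes with
#' canonical splice sites, an ATG start, a single terminal stop codon and no
#' internal stops.  Planted alternative exons are amino-acid-level mutated
#' copies of their source exon at the requested identity, installed inside
#' the requested intron behind an \code{AG} acceptor and in front of a
#' \code{GT} donor.  Every intron is screened with the package's own
#' enumerator at the relaxed store parameters and resampled until it
#' contains no chance candidate, so genomes without plants are clean
#' negative controls.
#'
#' @param spec a [PlantSpec-class].
#' @param outDir optional directory; when given, writes
#'   \code{genome.fasta}, \code{annotation.gff3}, \code{proteins.fasta} and
#'   \code{ground_truth.yaml}.
#' @return list with \code{genome} ([Biostrings::DNAStringSet]),
#'   \code{annotation} (data.frame as from [readAnnotation()]),
#'   \code{proteins} ([Biostrings::AAStringSet]) and \code{truth}
#'   (data.frame: one row per planted alternative with its genomic interval,
#'   source exon, identities, role and expected pass/fail under the display
#'   parameters).
#' @export
generatePlantedGenome <- function(spec, outDir = NULL) {
  res <- .withLocalSeed(spec@seed, .generatePlantedGenomeImpl(spec))
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writeGenome(res$genome, file.path(outDir, "genome.fasta"))
    writeAnnotationGFF3(res$annotation, file.path(outDir, "annotation.gff3"))
    writeXStringSet(res$proteins, file.path(outDir, "proteins.fasta"))
    writeLines(as.yaml(list(schema = "mxefinder-ground-truth",
                            seed = spec@seed,
                            plants = .dfToRows(res$truth)), precision = 17L),
               file.path(outDir, "ground_truth.yaml"))
  }
  res
}

.generatePlantedGenomeImpl <- function(spec) {
  contig <- character(0)
  offset <- 0L
  annRows <- list()
  truthRows <- list()
  flankRows <- list()
  protSeqs <- character(0)
  display <- predictionParams("display")

  for (g in seq_len(spec@nGenes)) {
    spacer <- .randNt(spec@intergenicNt)
    contig <- c(contig, spacer)
    offset <- offset + nchar(spacer)
    gl <- .buildLocalGene(spec, g)
    strand <- if (stats::runif(1) < spec@minusStrandProb) "-" else "+"
    L <- gl$length
    toGenomic <- function(s, e) {
      if (strand == "+") c(offset + s, offset + e)
      else c(offset + L - e, offset + L - s)
    }
    geneId <- sprintf("gene%03d", g)

    # isoform A: the primary annotation
    exG <- t(mapply(toGenomic, gl$exonStart, gl$exonEnd))
    isoA <- data.frame(geneId = geneId,
                       proteinId = paste0(geneId, ".1"),
                       targetId = "chr1",
                       start = exG[, 1], end = exG[, 2], strand = strand,
                       phase = gl$phases, stringsAsFactors = FALSE)
    annRows[[length(annRows) + 1L]] <- isoA
    protSeqs[paste0(geneId, ".1")] <- gl$pep

    # isoform B for annotated-MXE / cassette patterns uses the pattern
    # alternative planted in the downstream intron of exon 2
    if (gl$pattern != "single") {
      pt <- Filter(function(t) t$role == "pattern", gl$truth)[[1]]
      keep <- if (gl$pattern == "annotated_mxe")
        setdiff(seq_len(gl$nEx), 2L) else seq_len(gl$nEx)
      exB <- rbind(data.frame(s = gl$exonStart[keep], e = gl$exonEnd[keep]),
                   data.frame(s = pt$start, e = pt$end))
      exB <- exB[order(exB$s), , drop = FALSE]
      exBG <- t(mapply(toGenomic, exB$s, exB$e))
      isoB <- data.frame(geneId = geneId,
                         proteinId = paste0(geneId, ".2"),
                         targetId = "chr1",
                         start = exBG[, 1], end = exBG[, 2], strand = strand,
                         phase = 0L, stringsAsFactors = FALSE)
      annRows[[length(annRows) + 1L]] <- isoB
    }

    for (t in gl$truth) {
      gc <- toGenomic(t$start, t$end)
      srcG <- toGenomic(gl$exonStart[t$sourceExon], gl$exonEnd[t$sourceExon])
      srcPep <- exonPeptide(gl$exonNt[t$sourceExon], gl$phases[t$sourceExon])
      altPep <- exonPeptide(t$nt, gl$phases[t$sourceExon])
      sc <- similarityScore(srcPep, altPep, display)
      lenDiff <- abs(nchar(t$nt) - nchar(gl$exonNt[t$sourceExon])) %/% 3L
      srcAa <- nchar(gl$exonNt[t$sourceExon]) %/% 3L
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        geneId = geneId, sourceExonIndex = t$sourceExon,
        sourceStart = srcG[1], sourceEnd = srcG[2],
        start = gc[1], end = gc[2], strand = strand,
        targetIdentity = t$targetIdentity,
        realizedIdentity = t$realizedIdentity,
        lenOffset = t$lenOffset, role = t$role, score = sc,
        lenDiffAa = lenDiff,
        expectedPass = sc >= display@minScore &
          lenDiff <= display@maxLenDiff & srcAa >= display@minExonLen,
        stringsAsFactors = FALSE)
    }
    for (fc in gl$flankCopies) {
      gc <- toGenomic(fc$start, fc$end)
      flankRows[[length(flankRows) + 1L]] <- data.frame(
        geneId = geneId, sourceExonIndex = fc$sourceExon,
        start = gc[1], end = gc[2], strand = strand,
        stringsAsFactors = FALSE)
    }

    contig <- c(contig, if (strand == "-") .revComp(gl$seq) else gl$seq)
    offset <- offset + L
  }
  contig <- c(contig, .randNt(spec@intergenicNt))
  genomeSeq <- paste(contig, collapse = "")
  genome <- DNAStringSet(c(chr1 = genomeSeq))

  ann <- if (length(annRows)) do.call(rbind, annRows) else
    data.frame(geneId = character(0), proteinId = character(0),
               targetId = character(0), start = numeric(0), end = numeric(0),
               strand = character(0), phase = integer(0),
               stringsAsFactors = FALSE)
  # transcription order within isoforms
  if (nrow(ann)) {
    ord <- order(ann$geneId, ann$proteinId,
                 ifelse(ann$strand == "-", -ann$start, ann$start))
    ann <- ann[ord, , drop = FALSE]
    rownames(ann) <- NULL
    # phases must follow transcription order; recompute per isoform
    for (tx in unique(ann$proteinId)) {
      sel <- which(ann$proteinId == tx)
      nt <- as.integer(ann$end[sel] - ann$start[sel])
      ph <- integer(length(sel))
      for (i in seq_along(sel)[-1])
        ph[i] <- .nextPhase(nt[i - 1L], ph[i - 1L])
      ann$phase[sel] <- ph
    }
  }

  truth <- if (length(truthRows)) do.call(rbind, truthRows) else
    data.frame(geneId = character(0), sourceExonIndex = integer(0),
               sourceStart = numeric(0), sourceEnd = numeric(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               targetIdentity = numeric(0), realizedIdentity = numeric(0),
               lenOffset = integer(0), role = character(0),
               score = numeric(0), lenDiffAa = integer(0),
               expectedPass = logical(0), stringsAsFactors = FALSE)
  flankDf <- if (length(flankRows)) do.call(rbind, flankRows) else
    data.frame(geneId = character(0), sourceExonIndex = integer(0),
               start = numeric(0), end = numeric(0), strand = character(0),
               stringsAsFactors = FALSE)
  rownames(truth) <- NULL

  proteins <- AAStringSet(protSeqs)
  list(genome = genome, annotation = ann, proteins = proteins,
       truth = truth, flankCopies = flankDf)
}
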