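# The central search: enumerate splice-site-bounded, frame-preserving,
# length- and sequence-similar exon candidates for each original exon.

#' Similarity score between two exon peptides
#'
#' The similarity score is given in percent and defined as the global
#' alignment score of the original exon's peptide against the candidate's
#' peptide, divided by the self-alignment score of the original peptide:
#' \code{100 * align(orig, cand) / align(orig, orig)}.  Alignment is global
#' (end gaps penalized) under the configured substitution matrix and affine
#' gap penalties (a gap of length L costs \code{gapOpen + L * gapExtend}).
#' Identical peptides score exactly 100; unrelated peptides may score
#' negatively.
#'
#' @param original peptide of the original (annotated) exon; single
#'   non-empty string.
#' @param candidate peptide of the candidate exon; single non-empty string.
#' @param params a [PredictionParams-class] supplying matrix and gap
#'   penalties.
#' @return the score in percent.
#' @examples
#' similarityScore("MKVLAT", "MKVLAT")  # 100
#' @export
similarityScore <- function(original, candidate,
                            params = predictionParams()) {
  .scoreMany(original, candidate, params)
}

# vectorised scoring of many candidate peptides against one original
.scoreMany <- function(original, candidates, params) {
  if (!nzchar(original)) stop("similarity score: empty original peptide")
  if (!length(candidates)) return(numeric(0))
  if (any(!nzchar(candidates)))
    stop("similarity score: empty candidate peptide")
  mat <- .subMatrix(params@matrix)
  self <- pairwiseAlignment(AAString(original), AAString(original),
                            substitutionMatrix = mat,
                            gapOpening = params@gapOpen,
                            gapExtension = params@gapExtend,
                            type = "global", scoreOnly = TRUE)
  if (self <= 0)
    stop("similarity score: non-positive self-alignment score (degenerate ",
         "original peptide)")
  sc <- pairwiseAlignment(AAStringSet(candidates), AAString(original),
                          substitutionMatrix = mat,
                          gapOpening = params@gapOpen,
                          gapExtension = params@gapExtend,
                          type = "global", scoreOnly = TRUE)
  100 * sc / self
}

#' Reading-frame compatibility of two exon lengths
#'
#' A replacement exon preserves the reading frame of all downstream exons iff
#' its length differs from the original by a multiple of three nucleotides.
#'
#' @param original,candidate exon lengths in nucleotides (vectorised).
#' @return logical.
#' @examples
#' frameCompatible(60, 63)  # TRUE
#' frameCompatible(60, 62)  # FALSE
#' @export
frameCompatible <- function(original, candidate) {
  (candidate - original) %% 3L == 0L
}

# stop-codon screen for candidate peptides: internal stops always reject; a
# stop in the final complete codon is tolerated only for terminal source
# exons (where the original exon carries the stop itself)
.stopAllowed <- function(peptides, sourceIsTerminal) {
  n <- nchar(peptides)
  internal <- substr(peptides, 1L, pmax(0L, n - 1L))
  ok <- !grepl("\\*", internal, fixed = FALSE)
  last <- substr(peptides, n, n)
  if (!sourceIsTerminal) ok <- ok & last != "*"
  ok
}

#' Enumerate MXE candidates in one search region
#'
#' Exhaustively considers every exon candidate within the region that is
#' immediately preceded by an \code{AG} acceptor and immediately followed by
#' a \code{GT} or \code{GC} donor (on the coding strand), whose length is
#' frame-compatible with the original exon and within the length-difference
#' bound, whose complete codons (in the frame imposed by the original exon's
#' start phase) contain no disallowed stop codon, that keeps the configured
#' margin to both region edges, does not overlap the original exon, and whose
#' peptide scores at least \code{minScore} against the original exon's
#' peptide.  For flank regions the splice-site requirement on the gene-distal
#' side of initial/terminal source exons can be lifted.
#'
#' @param regionSeq region sequence on the coding strand.
#' @param regionStart,regionEnd genomic interval (0-based half-open, forward
#'   strand) the sequence was extracted from.
#' @param strand \code{"+"} or \code{"-"}.
#' @param sourceExon one-row exon data.frame (or list) with at least
#'   \code{start}, \code{end}, \code{ntLen}, \code{startPhase},
#'   \code{peptide}, \code{isTerminal}.
#' @param params a [PredictionParams-class].
#' @param requireAcceptor,requireDonor lift the acceptor/donor requirement
#'   (flank regions only).
#' @return data.frame with columns \code{start}, \code{end} (genomic),
#'   \code{ntLen}, \code{lenDiffAa}, \code{acceptor}, \code{donor},
#'   \code{score}, \code{peptide}.
#' @export
enumerateCandidates <- function(regionSeq, regionStart, regionEnd, strand,
                                sourceExon, params = predictionParams(),
                                requireAcceptor = TRUE, requireDonor = TRUE) {
  empty <- data.frame(start = numeric(0), end = numeric(0),
                      ntLen = integer(0), lenDiffAa = integer(0),
                      acceptor = character(0), donor = character(0),
                      score = numeric(0), peptide = character(0),
                      stringsAsFactors = FALSE)
  n <- nchar(regionSeq)
  margin <- params@minCandidateMargin
  srcNt <- as.integer(sourceExon$ntLen)
  phase <- as.integer(sourceExon$startPhase)
  srcPep <- sourceExon$peptide
  if (is.na(srcPep) || !nzchar(srcPep)) return(empty)
  if (n < srcNt - 3L * params@maxLenDiff) return(empty)

  # allowed frame-compatible lengths
  lens <- srcNt + 3L * seq(-params@maxLenDiff, params@maxLenDiff)
  lens <- lens[lens >= phase + 3L]    # at least one complete codon
  if (!length(lens)) return(empty)

  # splice-site anchor positions in local coding coordinates (1-based)
  accStarts <- integer(0)   # candidate start positions preceded by AG
  if (requireAcceptor) {
    m <- gregexpr("AG", regionSeq, fixed = TRUE)[[1]]
    if (m[1] != -1L) accStarts <- as.integer(m) + 2L
  }
  donEnds <- integer(0)     # candidate end positions followed by GT/GC
  if (requireDonor) {
    m <- gregexpr("G[TC]", regionSeq)[[1]]
    if (m[1] != -1L) donEnds <- as.integer(m) - 1L
  }

  minStart <- max(1L, as.integer(margin) + 1L, if (requireAcceptor) 3L else 1L)
  maxEnd <- n - as.integer(margin)

  if (requireAcceptor && requireDonor) {
    accSet <- accStarts[accStarts >= minStart]
    donSet <- donEnds[donEnds <= maxEnd & donEnds >= 1L]
    if (!length(accSet) || !length(donSet)) return(empty)
    grid <- expand.grid(end = donSet, L = lens)
    grid$start <- grid$end - grid$L + 1L
    keep <- grid$start %in% accSet
    grid <- grid[keep, , drop = FALSE]
  } else if (!requireAcceptor) {
    donSet <- donEnds[donEnds <= maxEnd & donEnds >= 1L]
    if (!length(donSet)) return(empty)
    grid <- expand.grid(end = donSet, L = lens)
    grid$start <- grid$end - grid$L + 1L
    grid <- grid[grid$start >= minStart, , drop = FALSE]
  } else {
    accSet <- accStarts[accStarts >= minStart]
    if (!length(accSet)) return(empty)
    grid <- expand.grid(start = accSet, L = lens)
    grid$end <- grid$start + grid$L - 1L
    grid <- grid[grid$end <= maxEnd, , drop = FALSE]
  }
  if (!nrow(grid)) return(empty)

  seqs <- substring(regionSeq, grid$start, grid$end)
  hasN <- grepl("N", seqs, fixed = TRUE)
  if (any(hasN)) {
    warning("search region contains ambiguous bases; ", sum(hasN),
            " candidate(s) spanning N skipped")
    grid <- grid[!hasN, , drop = FALSE]
    seqs <- seqs[!hasN]
  }
  if (!nrow(grid)) return(empty)

  # genomic interval and overlap screen against the original exon
  gcoord <- t(vapply(seq_len(nrow(grid)), function(i)
    .localToGenomic(grid$start[i], grid$end[i], regionStart, regionEnd,
                    strand), numeric(2)))
  keep <- !.overlaps(gcoord[, 1], gcoord[, 2],
                     sourceExon$start, sourceExon$end)
  grid <- grid[keep, , drop = FALSE]
  seqs <- seqs[keep]
  gcoord <- gcoord[keep, , drop = FALSE]
  if (!nrow(grid)) return(empty)

  # stop-codon screen in the frame imposed by the source exon's start phase
  peps <- .translateCodonsMany(substr(seqs, phase + 1L, nchar(seqs)))
  ok <- nzchar(peps) & .stopAllowed(peps, isTRUE(sourceExon$isTerminal))
  grid <- grid[ok, , drop = FALSE]
  seqs <- seqs[ok]
  peps <- peps[ok]
  gcoord <- gcoord[ok, , drop = FALSE]
  if (!nrow(grid)) return(empty)

  scores <- .scoreMany(srcPep, peps, params)
  ok <- scores >= params@minScore
  if (!any(ok)) return(empty)
  grid <- grid[ok, , drop = FALSE]
  peps <- peps[ok]
  scores <- scores[ok]
  gcoord <- gcoord[ok, , drop = FALSE]

  acc <- ifelse(grid$start >= 3L,
                substring(regionSeq, grid$start - 2L, grid$start - 1L), "")
  don <- ifelse(grid$end + 2L <= n,
                substring(regionSeq, grid$end + 1L, grid$end + 2L), "")
  out <- data.frame(start = gcoord[, 1], end = gcoord[, 2],
                    ntLen = as.integer(grid$L),
                    lenDiffAa = abs(as.integer(grid$L) - srcNt) %/% 3L,
                    acceptor = acc, donor = don, score = scores,
                    peptide = peps, stringsAsFactors = FALSE)
  out <- out[order(out$start, out$end), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Resolve mutually overlapping candidates within one search region
#'
#' Among mutually overlapping candidates only the best is kept: highest
#' score, ties broken by smaller length difference, then by 5'-most genomic
#' start.  Non-overlapping candidates are all retained.
#'
#' @param cands candidate data.frame with \code{start}, \code{end},
#'   \code{score}, \code{lenDiffAa}.
#' @return the surviving rows, in genomic order.
#' @export
resolveOverlappingCandidates <- function(cands) {
  if (nrow(cands) <= 1L) return(cands)
  ord <- order(-cands$score, cands$lenDiffAa, cands$start)
  kept <- integer(0)
  for (i in ord) {
    if (!length(kept) ||
        !any(.overlaps(cands$start[i], cands$end[i],
                       cands$start[kept], cands$end[kept])))
      kept <- c(kept, i)
  }
  out <- cands[sort(kept), , drop = FALSE]
  rownames(out) <- NULL
  out
}

# search regions (genomic intervals + location classes + splice-site
# requirements) for one exon of one isoform
.searchRegions <- function(iso, exonIdx, gene, genome, params) {
  ex <- iso@exons
  iv <- iso@introns
  n <- nrow(ex)
  regions <- list()
  addRegion <- function(start, end, location, reqAcc = TRUE, reqDon = TRUE) {
    if (end - start < 1) return()
    regions[[length(regions) + 1L]] <<- list(
      start = start, end = end, location = location,
      requireAcceptor = reqAcc, requireDonor = reqDon)
  }
  upIdx <- exonIdx - 1L   # transcription-order intron indices
  dnIdx <- exonIdx
  intronIdxSet <- if (params@scope == "all") seq_len(nrow(iv)) else
    intersect(c(upIdx, dnIdx), seq_len(nrow(iv)))
  for (k in intronIdxSet) {
    loc <- if (k == upIdx) "upstream_intron"
           else if (k == dnIdx) "downstream_intron" else "other_intron"
    addRegion(iv$start[k], iv$end[k], loc)
  }
  if (params@flankNt > 0) {
    tlen <- width(genome)[match(gene@targetId, names(genome))]
    fl <- params@flankNt
    if (gene@strand == "+") {
      addRegion(max(0, gene@locusStart - fl), gene@locusStart,
                "upstream_flank", reqAcc = !ex$isInitial[exonIdx])
      addRegion(gene@locusEnd, min(tlen, gene@locusEnd + fl),
                "downstream_flank", reqDon = !ex$isTerminal[exonIdx])
    } else {
      addRegion(gene@locusEnd, min(tlen, gene@locusEnd + fl),
                "upstream_flank", reqAcc = !ex$isInitial[exonIdx])
      addRegion(max(0, gene@locusStart - fl), gene@locusStart,
                "downstream_flank", reqDon = !ex$isTerminal[exonIdx])
    }
  }
  regions
}

#' Predict MXE candidates for one gene
#'
#' Runs the candidate search independently for each isoform: every original
#' exon of at least \code{minExonLen} amino acids seeds a search of the
#' regions implied by the scope (the introns flanking the exon, or all
#' introns, plus \code{flankNt} nucleotides up- and downstream of the gene
#' locus when enabled).  Candidates in each region are reduced with
#' [resolveOverlappingCandidates()] and labelled with their location class
#' relative to the source exon.
#'
#' @param gene a [GeneModel-class].
#' @param genome the genome ([Biostrings::DNAStringSet]).
#' @param params a [PredictionParams-class].
#' @return candidate data.frame (see package overview); zero rows when the
#'   gene offers no search region.
#' @export
predictGene <- function(gene, genome, params = predictionParams()) {
  out <- list()
  for (iso in gene@isoforms) {
    ex <- iso@exons
    for (e in seq_len(nrow(ex))) {
      if (ex$aaLen[e] < params@minExonLen) next
      if (is.na(ex$peptide[e]) || !nzchar(ex$peptide[e])) next
      regions <- .searchRegions(iso, e, gene, genome, params)
      for (rg in regions) {
        regionSeq <- .codingSeq(genome, gene@targetId, rg$start, rg$end,
                                iso@strand)
        cands <- enumerateCandidates(regionSeq, rg$start, rg$end,
                                     iso@strand, ex[e, , drop = FALSE],
                                     params,
                                     requireAcceptor = rg$requireAcceptor,
                                     requireDonor = rg$requireDonor)
        if (!nrow(cands)) next
        cands <- resolveOverlappingCandidates(cands)
        flankDist <- if (rg$location %in% c("upstream_flank",
                                            "downstream_flank")) {
          pmax(gene@locusStart - cands$start, cands$end - gene@locusEnd)
        } else NA_real_
        out[[length(out) + 1L]] <- data.frame(
          candidateId = NA_character_, geneId = gene@geneId,
          proteinId = iso@proteinId, sourceExonIndex = as.integer(e),
          sourceExonStart = ex$start[e], sourceExonEnd = ex$end[e],
          sourceNtLen = ex$ntLen[e], sourceAaLen = ex$aaLen[e],
          targetId = gene@targetId, start = cands$start, end = cands$end,
          strand = iso@strand, location = rg$location,
          acceptor = cands$acceptor, donor = cands$donor,
          ntLen = cands$ntLen, lenDiffAa = cands$lenDiffAa,
          score = cands$score, peptide = cands$peptide,
          flankDistNt = flankDist, flagExactMatch = FALSE,
          flagIsoformOverlap = FALSE, flagNeighbourOverlap = FALSE,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) return(.emptyCandidates())
  df <- do.call(rbind, out)
  df <- .orderCandidates(df)
  df <- .assignCandidateIds(df)
  rownames(df) <- NULL
  df
}

#' Run the full MXE prediction pipeline on a dataset
#'
#' Reads (or accepts) the genome and annotation, builds gene models, predicts
#' candidates for every gene, reconciles candidates across isoforms and
#' neighbouring genes, applies the run's filter parameters, assembles and
#' classifies clusters, detects annotated MXE clusters and MXE-like
#' constitutive exons, and summarises the dataset.
#'
#' With the relaxed \code{"store"} preset this reproduces the pipeline
#' design: a permissive candidate store that can later be re-filtered with
#' stricter display values via [filterResult()] without re-running the
#' search.
#'
#' @param genome a [Biostrings::DNAStringSet] or path to a genome FASTA.
#' @param annotation an annotation data.frame (from [readAnnotation()]) or
#'   path to a GFF3 file.
#' @param params a [PredictionParams-class]; default the strict display
#'   preset.
#' @param dataset dataset name recorded in outputs.
#' @param proteins optional [Biostrings::AAStringSet] or path to a protein
#'   FASTA for the translation cross-check.
#' @param seed optional integer recorded in the output metadata.
#' @return an [MXEResult-class].
#' @export
predictMXE <- function(genome, annotation, params = predictionParams(),
                       dataset = "dataset", proteins = NULL, seed = NA) {
  if (is.character(genome)) genome <- readGenome(genome)
  if (is.character(annotation)) annotation <- readAnnotation(annotation, genome)
  if (is.character(proteins)) {
    aa <- readBStringSet(proteins)
    names(aa) <- sub("\\s.*$", "", names(aa))
    proteins <- AAStringSet(toupper(as.character(aa)))
  }
  models <- buildGeneModels(annotation, genome, proteins = proteins)

  cands <- .emptyCandidates()
  for (gene in models) {
    gc <- predictGene(gene, genome, params)
    if (nrow(gc)) gc <- reconcileIsoforms(gene, gc)
    cands <- rbind(cands, gc)
  }
  .assembleResult(dataset, params, seed, genome, models, cands)
}

# shared by predictMXE and filterResult: everything downstream of the raw
# candidate table
.assembleResult <- function(dataset, params, seed, genome, models, cands) {
  surviving <- applyFilters(cands, params)$candidates
  clusters <- list()
  annotated <- list()
  constLike <- .emptyConstitutiveLike()
  for (gene in models) {
    gs <- surviving[surviving$geneId == gene@geneId, , drop = FALSE]
    clusters <- c(clusters, assembleClusters(gene, gs))
    annotated <- c(annotated, detectAnnotatedMXEClusters(gene))
    constLike <- rbind(constLike, detectConstitutiveMXELike(gene, params))
  }
  targets <- data.frame(id = names(genome), length = as.numeric(width(genome)),
                        stringsAsFactors = FALSE)
  summ <- summarizeExome(models, clusters, annotated, constLike, surviving)
  new("MXEResult", dataset = dataset, params = params,
      seed = as.numeric(seed), targets = targets, geneModels = models,
      candidates = cands, clusters = clusters, annotatedClusters = annotated,
      constitutiveLike = constLike, summary = summ)
}

#' Re-filter a stored result with new display parameters
#'
#' Filtering is pure: no re-prediction happens.  The full candidate table is
#' kept; clusters and the summary are recomputed from the candidates
#' surviving the new parameters.  Gene models are required for cluster
#' assembly: pass a result that still carries them, or supply the genome and
#' annotation of the original run.
#'
#' @param result an [MXEResult-class].
#' @param params the new [PredictionParams-class].
#' @param genome,annotation optional; used to rebuild gene models when
#'   \code{result} comes from YAML and carries none.
#' @return a new [MXEResult-class].
#' @export
filterResult <- function(result, params, genome = NULL, annotation = NULL) {
  models <- result@geneModels
  if (!length(models)) {
    if (is.null(genome) || is.null(annotation))
      stop("result carries no gene models; supply genome and annotation")
    if (is.character(genome)) genome <- readGenome(genome)
    if (is.character(annotation))
      annotation <- readAnnotation(annotation, genome)
    models <- buildGeneModels(annotation, genome)
  }
  genome2 <- if (is.null(genome)) {
    # reconstruct a minimal width table for summary targets
    DNAStringSet(stats::setNames(
      vapply(result@targets$length, function(l)
        paste(rep("N", 0L), collapse = ""), character(1)),
      result@targets$id))
  } else genome
  res <- .assembleResult(result@dataset, params, result@seed,
                         genome2, models, result@candidates)
  if (is.null(genome)) res@targets <- result@targets
  res@geneModels <- models
  res
}
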