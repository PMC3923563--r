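# Fabricated gene models and candidate rows for unit-testing the cluster
# logic without running the full search.

makeIso <- function(proteinId, starts, ends, peptides = NULL, strand = "+",
                    targetId = "chr1") {
  n <- length(starts)
  ntLen <- as.integer(ends - starts)
  if (is.null(peptides)) peptides <- strrep("A", ntLen %/% 3L)
  phases <- integer(n)
  for (i in seq_len(n)[-1])
    phases[i] <- (3L - ((ntLen[i - 1] - phases[i - 1]) %% 3L)) %% 3L
  ex <- data.frame(index = seq_len(n), start = starts, end = ends,
                   startPhase = phases, ntLen = ntLen, aaLen = ntLen %/% 3L,
                   peptide = peptides, displayPeptide = peptides,
                   isInitial = seq_len(n) == 1L, isTerminal = seq_len(n) == n,
                   stringsAsFactors = FALSE)
  iv <- if (n > 1)
    data.frame(index = seq_len(n - 1L), start = ends[-n], end = starts[-1])
  else data.frame(index = integer(0), start = numeric(0), end = numeric(0))
  new("Isoform", proteinId = proteinId, targetId = targetId, strand = strand,
      exons = ex, introns = iv, completeness = "complete",
      issues = character(0))
}

makeGene <- function(geneId, isoList, neighbourExons = NULL,
                     strand = "+", targetId = "chr1") {
  if (is.null(neighbourExons))
    neighbourExons <- data.frame(geneId = character(0), start = numeric(0),
                                 end = numeric(0), stringsAsFactors = FALSE)
  allEx <- do.call(rbind, lapply(isoList, function(i)
    i@exons[, c("start", "end")]))
  new("GeneModel", geneId = geneId, targetId = targetId, strand = strand,
      locusStart = min(allEx$start), locusEnd = max(allEx$end),
      isoforms = isoList, neighbourExons = neighbourExons)
}

candRows <- function(geneId, proteinId, sourceExonIndex, sourceStart,
                     sourceEnd, start, end, score = 50,
                     location = "downstream_intron", strand = "+",
                     peptide = "AAAA") {
  n <- length(start)
  df <- data.frame(
    candidateId = paste0("c", seq_len(n), "-", geneId, "-", start),
    geneId = geneId, proteinId = proteinId,
    sourceExonIndex = as.integer(sourceExonIndex),
    sourceExonStart = sourceStart, sourceExonEnd = sourceEnd,
    sourceNtLen = as.integer(sourceEnd - sourceStart),
    sourceAaLen = as.integer(sourceEnd - sourceStart) %/% 3L,
    targetId = "chr1", start = start, end = end, strand = strand,
    location = location, acceptor = "AG", donor = "GT",
    ntLen = as.integer(end - start),
    lenDiffAa = abs(as.integer(end - start) -
                      as.integer(sourceEnd - sourceStart)) %/% 3L,
    score = score, peptide = peptide, flankDistNt = NA_real_,
    flagExactMatch = FALSE, flagIsoformOverlap = FALSE,
    flagNeighbourOverlap = FALSE, stringsAsFactors = FALSE)
  df
}
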