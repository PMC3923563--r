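# Gene-model reconstruction from an annotation table: exon phases, peptides,
# derived introns, and structural validation (splice-site patterns, internal
# and terminal stop codons, frame consistency, optional protein cross-check).

#' Translate an exon's complete codons
#'
#' Skips \code{startPhase} nucleotides (GFF3 phase semantics: the number of
#' bases to reach the first complete codon), translates complete codons with
#' the standard nuclear genetic code and drops any trailing partial codon.
#' Stop codons are rendered as \code{"*"}.
#'
#' @param seq exon nucleotide sequence on the coding strand (A, C, G, T).
#' @param startPhase 0, 1 or 2.
#' @return the peptide as a single string (may be empty for exons shorter
#'   than one complete codon).
#' @examples
#' exonPeptide("ATGGCC", 0)   # "MA"
#' exonPeptide("AATGGCC", 1)  # "MA"
#' @export
exonPeptide <- function(seq, startPhase = 0L) {
  if (grepl("[^ACGT]", seq))
    stop("exonPeptide: sequence contains characters outside A,C,G,T ",
         "(ambiguous bases must be screened by the caller)")
  if (!startPhase %in% 0:2) stop("startPhase must be 0, 1 or 2")
  if (nchar(seq) <= startPhase) return("")
  .translateCodons(substr(seq, startPhase + 1L, nchar(seq)))
}

# phase chain: phase of the next exon given this exon's phase and length
.nextPhase <- function(ntLen, startPhase) (3L - ((ntLen - startPhase) %% 3L)) %% 3L

.stopCodons <- c("TAA", "TAG", "TGA")

# concatenated coding sequence of an exon table (coding strand, transcription
# order)
.isoformCDS <- function(exonsDf, genome, targetId, strand) {
  paste(vapply(seq_len(nrow(exonsDf)), function(i)
    .codingSeq(genome, targetId, exonsDf$start[i], exonsDf$end[i], strand),
    character(1)), collapse = "")
}

#' Validate the structure of an isoform
#'
#' Flags introns whose splice sites do not match the canonical
#' \code{GT...AG} or \code{GC...AG} pattern on the coding strand, in-frame
#' internal stop codons, a missing terminal stop codon, CDS lengths
#' inconsistent with the phase chain and, when a reference protein is given,
#' any mismatch between the translation and that protein.  Validation never
#' raises on biological defects; it labels.  Any flag marks the isoform
#' incomplete.
#'
#' @param isoform an [Isoform-class] object.
#' @param genome the genome ([Biostrings::DNAStringSet]).
#' @param protein optional reference protein sequence (single string, no
#'   terminal \code{*}).
#' @return list with elements \code{completeness} (\code{"complete"} or
#'   \code{"incomplete"}) and \code{issues} (character vector drawn from
#'   \code{noncanonical_intron}, \code{internal_stop}, \code{missing_stop},
#'   \code{frame_inconsistency}, \code{protein_mismatch},
#'   \code{ambiguous_bases}).
#' @export
validateStructure <- function(isoform, genome, protein = NULL) {
  ex <- isoform@exons
  iv <- isoform@introns
  issues <- character(0)

  for (i in seq_len(nrow(iv))) {
    iseq <- .codingSeq(genome, isoform@targetId, iv$start[i], iv$end[i],
                       isoform@strand)
    if (nchar(iseq) < 4L) { issues <- c(issues, "noncanonical_intron"); next }
    don <- substr(iseq, 1L, 2L)
    acc <- substr(iseq, nchar(iseq) - 1L, nchar(iseq))
    if (!(don %in% c("GT", "GC") && acc == "AG"))
      issues <- c(issues, "noncanonical_intron")
  }

  cdsSeq <- .isoformCDS(ex, genome, isoform@targetId, isoform@strand)
  if (grepl("[^ACGT]", cdsSeq)) {
    issues <- c(issues, "ambiguous_bases")
  } else {
    p0 <- ex$startPhase[1]
    coding <- substr(cdsSeq, p0 + 1L, nchar(cdsSeq))
    if (nchar(coding) %% 3L != 0L)
      issues <- c(issues, "frame_inconsistency")
    pep <- .translateCodons(coding)
    if (nchar(pep) > 1L && grepl("\\*", substr(pep, 1L, nchar(pep) - 1L)))
      issues <- c(issues, "internal_stop")
    lastCodon <- if (nchar(coding) >= 3L)
      substr(coding, 3L * (nchar(coding) %/% 3L) - 2L,
             3L * (nchar(coding) %/% 3L)) else ""
    if (!lastCodon %in% .stopCodons)
      issues <- c(issues, "missing_stop")
    if (!is.null(protein)) {
      trans <- sub("\\*$", "", pep)
      if (!identical(trans, protein))
        issues <- c(issues, "protein_mismatch")
    }
  }

  # declared GFF3 phases must agree with the arithmetic chain
  if (nrow(ex) > 1) {
    for (i in seq_len(nrow(ex) - 1L)) {
      expected <- .nextPhase(ex$ntLen[i], ex$startPhase[i])
      if (ex$startPhase[i + 1L] != expected) {
        issues <- c(issues, "frame_inconsistency")
        break
      }
    }
  }

  issues <- unique(issues)
  list(completeness = if (length(issues)) "incomplete" else "complete",
       issues = issues)
}

# build one Isoform from its CDS segment rows (transcription order)
.buildIsoform <- function(rows, genome, protein = NULL) {
  n <- nrow(rows)
  strand <- rows$strand[1]
  targetId <- rows$targetId[1]
  ntLen <- as.integer(rows$end - rows$start)

  phases <- rows$phase
  if (is.na(phases[1])) phases[1] <- 0L
  for (i in seq_len(n)[-1]) {
    if (is.na(phases[i]))
      phases[i] <- .nextPhase(ntLen[i - 1L], phases[i - 1L])
  }

  seqs <- vapply(seq_len(n), function(i)
    .codingSeq(genome, targetId, rows$start[i], rows$end[i], strand),
    character(1))
  hasAmbig <- grepl("[^ACGT]", seqs)
  peptide <- ifelse(hasAmbig, NA_character_, mapply(function(s, p)
    if (nchar(s) > p) .translateCodons(substr(s, p + 1L, nchar(s))) else "",
    seqs, phases, USE.NAMES = FALSE))

  # display peptides: each codon attributed to the exon containing its first
  # nucleotide, so concatenation reproduces the full CDS translation
  displayPeptide <- rep(NA_character_, n)
  if (!any(hasAmbig)) {
    cds <- paste(seqs, collapse = "")
    fullPep <- if (nchar(cds) > phases[1])
      .translateCodons(substr(cds, phases[1] + 1L, nchar(cds))) else ""
    exonOfNt <- rep(seq_len(n), ntLen)
    codonStartNt <- phases[1] + 1L + 3L * (seq_len(nchar(fullPep)) - 1L)
    codonExon <- exonOfNt[codonStartNt]
    displayPeptide <- vapply(seq_len(n), function(i)
      paste(strsplit(fullPep, "")[[1]][codonExon == i], collapse = ""),
      character(1))
  }

  exonsDf <- data.frame(
    index = seq_len(n), start = rows$start, end = rows$end,
    startPhase = as.integer(phases), ntLen = ntLen,
    aaLen = ntLen %/% 3L, peptide = peptide,
    displayPeptide = displayPeptide,
    isInitial = seq_len(n) == 1L, isTerminal = seq_len(n) == n,
    stringsAsFactors = FALSE)

  intronsDf <- if (n > 1) {
    if (strand == "-") {
      data.frame(index = seq_len(n - 1L),
                 start = rows$end[-1], end = rows$start[-n])
    } else {
      data.frame(index = seq_len(n - 1L),
                 start = rows$end[-n], end = rows$start[-1])
    }
  } else {
    data.frame(index = integer(0), start = numeric(0), end = numeric(0))
  }

  iso <- new("Isoform", proteinId = rows$proteinId[1], targetId = targetId,
             strand = strand, exons = exonsDf, introns = intronsDf,
             completeness = "complete", issues = character(0))
  v <- validateStructure(iso, genome, protein = protein)
  iso@completeness <- v$completeness
  iso@issues <- v$issues
  iso
}

#' Build validated gene models
#'
#' Groups the annotation table per gene and isoform, propagates exon phases
#' (GFF3 phase where given, arithmetic chain otherwise), translates exon
#' peptides from the coding strand, derives introns, validates every isoform
#' (see [validateStructure()]) and records the exon intervals of adjacent
#' genes for neighbour-overlap flagging.  Isoforms with structural issues are
#' marked incomplete but are retained and searched.
#'
#' @param ann annotation data.frame from [readAnnotation()].
#' @param genome the genome ([Biostrings::DNAStringSet]).
#' @param proteins optional named [Biostrings::AAStringSet] (names matching
#'   protein ids) enabling the translation cross-check.
#' @return named list of [GeneModel-class] objects.
#' @export
buildGeneModels <- function(ann, genome, proteins = NULL) {
  if (!nrow(ann)) return(list())
  genes <- list()
  for (g in unique(ann$geneId)) {
    ga <- ann[ann$geneId == g, , drop = FALSE]
    isoList <- lapply(unique(ga$proteinId), function(tx) {
      rows <- ga[ga$proteinId == tx, , drop = FALSE]
      prot <- if (!is.null(proteins) && tx %in% names(proteins))
        as.character(proteins[[tx]]) else NULL
      .buildIsoform(rows, genome, protein = prot)
    })
    allEx <- do.call(rbind, lapply(isoList, function(i)
      i@exons[, c("start", "end")]))
    genes[[g]] <- new("GeneModel", geneId = g, targetId = ga$targetId[1],
                      strand = ga$strand[1],
                      locusStart = min(allEx$start), locusEnd = max(allEx$end),
                      isoforms = isoList,
                      neighbourExons = data.frame(geneId = character(0),
                                                  start = numeric(0),
                                                  end = numeric(0),
                                                  stringsAsFactors = FALSE))
  }

  # neighbour context: exon intervals of the flanking genes on each target
  info <- data.frame(geneId = names(genes),
                     targetId = vapply(genes, slot, character(1), "targetId"),
                     locusStart = vapply(genes, slot, numeric(1), "locusStart"),
                     stringsAsFactors = FALSE)
  for (tid in unique(info$targetId)) {
    ids <- info$geneId[info$targetId == tid]
    ids <- ids[order(info$locusStart[match(ids, info$geneId)])]
    for (k in seq_along(ids)) {
      nb <- ids[stats::na.omit(c(if (k > 1) k - 1L else NA,
                                 if (k < length(ids)) k + 1L else NA))]
      if (!length(nb)) next
      nbEx <- do.call(rbind, lapply(nb, function(ng) {
        ex <- unique(do.call(rbind, lapply(genes[[ng]]@isoforms, function(i)
          i@exons[, c("start", "end")])))
        data.frame(geneId = ng, start = ex$start, end = ex$end,
                   stringsAsFactors = FALSE)
      }))
      genes[[ids[k]]]@neighbourExons <- nbEx
    }
  }
  genes
}
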