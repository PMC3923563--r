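# Dataset-level statistics and sensitivity against annotated MXEs.

#' Summarise a mutually exclusive exome
#'
#' Produces the per-dataset count schema used for whole-exome reports:
#' gene/protein counts, genes with multiple exons, genes with predicted MXE
#' candidates, genes with MXEs already present in the annotation, genes with
#' constitutive exons matching the MXE criteria, and the corresponding exon
#' counts plus per-type cluster counts.  Exon counts are of distinct genomic
#' exons: an exon shared by several isoforms is counted once.
#'
#' @param geneModels list of [GeneModel-class].
#' @param clusters list of predicted [MXECluster-class].
#' @param annotatedClusters list of annotated [MXECluster-class].
#' @param constitutiveLike data.frame from [detectConstitutiveMXELike()].
#' @param surviving candidate data.frame after filtering.
#' @return one-row data.frame of counts.
#' @export
summarizeExome <- function(geneModels, clusters, annotatedClusters,
                           constitutiveLike, surviving) {
  genes <- length(geneModels)
  proteins <- sum(vapply(geneModels, function(g) length(g@isoforms),
                         integer(1)))
  multiExon <- sum(vapply(geneModels, function(g)
    any(vapply(g@isoforms, function(i) nrow(i@exons) >= 2L, logical(1))),
    logical(1)))
  exonsAnnotated <- sum(vapply(geneModels, function(g)
    nrow(unique(do.call(rbind, lapply(g@isoforms, function(i)
      i@exons[, c("start", "end")])))), integer(1)))

  predGenes <- length(unique(surviving$geneId))
  predExons <- if (nrow(surviving))
    nrow(unique(surviving[, c("geneId", "start", "end")])) else 0L

  annGenes <- length(unique(vapply(annotatedClusters, slot, character(1),
                                   "geneId")))
  annExons <- if (length(annotatedClusters))
    sum(vapply(annotatedClusters, function(cl) nrow(cl@members), integer(1)))
  else 0L

  clGenes <- length(unique(constitutiveLike$geneId))
  clExons <- if (nrow(constitutiveLike))
    nrow(unique(rbind(
      data.frame(geneId = constitutiveLike$geneId,
                 start = constitutiveLike$startA,
                 end = constitutiveLike$endA),
      data.frame(geneId = constitutiveLike$geneId,
                 start = constitutiveLike$startB,
                 end = constitutiveLike$endB)))) else 0L

  types <- vapply(clusters, slot, character(1), "type")
  data.frame(
    genes = genes, proteins = proteins, genesMultiExon = multiExon,
    genesPredictedMXE = predGenes, genesAnnotatedMXE = annGenes,
    genesConstitutiveMXELike = clGenes, exonsAnnotated = exonsAnnotated,
    predictedMXEExons = predExons, annotatedMXEExons = annExons,
    constitutiveMXELikeExons = clExons,
    clustersInitial = sum(types == "initial"),
    clustersInternal = sum(types == "internal"),
    clustersTerminal = sum(types == "terminal"),
    stringsAsFactors = FALSE)
}

#' Sensitivity of the prediction against annotated MXEs
#'
#' An annotated MXE counts as reconstructed iff some predicted candidate,
#' sourced from a different exon of its cluster, matches its genomic
#' interval exactly (both boundaries).  The comparison is restricted to
#' internal clusters by default: initial and terminal clusters can arise
#' from multiple promoters or multiple poly(A) sites rather than from
#' splicing.
#'
#' @param candidates predicted candidate data.frame (filtered with the same
#'   parameters used for the comparison).
#' @param annotatedClusters list of annotated [MXECluster-class] from
#'   [detectAnnotatedMXEClusters()].
#' @param restrict \code{"internal"} (default) or \code{"all"}.
#' @return list with \code{considered}, \code{reconstructed} and
#'   \code{sensitivity} (percent; \code{NA} when no annotated MXE is
#'   considered).
#' @export
computeSensitivity <- function(candidates, annotatedClusters,
                               restrict = c("internal", "all")) {
  restrict <- match.arg(restrict)
  cls <- annotatedClusters
  if (restrict == "internal")
    cls <- Filter(function(cl) cl@type == "internal", cls)
  considered <- 0L
  reconstructed <- 0L
  for (cl in cls) {
    mem <- cl@members
    memKey <- paste(mem$start, mem$end)
    cc <- candidates[candidates$geneId == cl@geneId, , drop = FALSE]
    for (i in seq_len(nrow(mem))) {
      considered <- considered + 1L
      hit <- cc$start == mem$start[i] & cc$end == mem$end[i] &
        paste(cc$sourceExonStart, cc$sourceExonEnd) %in%
          memKey[-i]
      if (any(hit)) reconstructed <- reconstructed + 1L
    }
  }
  list(considered = considered, reconstructed = reconstructed,
       sensitivity = if (considered)
         100 * reconstructed / considered else NA_real_)
}
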