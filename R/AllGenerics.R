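# Accessor generics, methods and show() methods.

#' @rdname MXEResult-class
#' @param object,x an object.
#' @export
setGeneric("candidates", function(x) standardGeneric("candidates"))
#' @rdname MXEResult-class
#' @export
setGeneric("clusters", function(x) standardGeneric("clusters"))
#' @rdname MXEResult-class
#' @export
setGeneric("annotatedClusters", function(x) standardGeneric("annotatedClusters"))
#' @rdname MXEResult-class
#' @export
setGeneric("params", function(x) standardGeneric("params"))
#' @rdname MXEResult-class
#' @export
setGeneric("geneModels", function(x) standardGeneric("geneModels"))
#' @rdname MXEResult-class
#' @export
setGeneric("exomeSummary", function(x) standardGeneric("exomeSummary"))
#' @rdname GeneModel-class
#' @param x an object.
#' @export
setGeneric("isoforms", function(x) standardGeneric("isoforms"))
#' @rdname Isoform-class
#' @param x an object.
#' @export
setGeneric("exons", function(x) standardGeneric("exons"))
#' @rdname Isoform-class
#' @export
setGeneric("introns", function(x) standardGeneric("introns"))
#' @rdname Isoform-class
#' @export
setGeneric("completeness", function(x) standardGeneric("completeness"))
#' @rdname Isoform-class
#' @export
setGeneric("issues", function(x) standardGeneric("issues"))
#' @rdname MXECluster-class
#' @param x an object.
#' @export
setGeneric("members", function(x) standardGeneric("members"))
#' @rdname MXECluster-class
#' @export
setGeneric("clusterType", function(x) standardGeneric("clusterType"))

#' @rdname MXEResult-class
#' @export
setMethod("candidates", "MXEResult", function(x) x@candidates)
#' @rdname MXEResult-class
#' @export
setMethod("clusters", "MXEResult", function(x) x@clusters)
#' @rdname MXEResult-class
#' @export
setMethod("annotatedClusters", "MXEResult", function(x) x@annotatedClusters)
#' @rdname MXEResult-class
#' @export
setMethod("params", "MXEResult", function(x) x@params)
#' @rdname MXEResult-class
#' @export
setMethod("geneModels", "MXEResult", function(x) x@geneModels)
#' @rdname MXEResult-class
#' @export
setMethod("exomeSummary", "MXEResult", function(x) x@summary)

#' @rdname GeneModel-class
#' @export
setMethod("isoforms", "GeneModel", function(x) x@isoforms)
#' @rdname Isoform-class
#' @export
setMethod("exons", "Isoform", function(x) x@exons)
#' @rdname Isoform-class
#' @export
setMethod("introns", "Isoform", function(x) x@introns)
#' @rdname Isoform-class
#' @export
setMethod("completeness", "Isoform", function(x) x@completeness)
#' @rdname Isoform-class
#' @export
setMethod("issues", "Isoform", function(x) x@issues)
#' @rdname MXECluster-class
#' @export
setMethod("members", "MXECluster", function(x) x@members)
#' @rdname MXECluster-class
#' @export
setMethod("clusterType", "MXECluster", function(x) x@type)

setMethod("show", "PredictionParams", function(object) {
  cat("PredictionParams\n")
  cat(sprintf("  minScore: %g%%  maxLenDiff: %g aa  minExonLen: %g aa\n",
              object@minScore, object@maxLenDiff, object@minExonLen))
  cat(sprintf("  scope: %s  flankNt: %g  margin: %g nt\n",
              object@scope, object@flankNt, object@minCandidateMargin))
  cat(sprintf("  alignment: %s, gap open %g / extend %g\n",
              object@matrix, object@gapOpen, object@gapExtend))
  cat(sprintf("  excludeIsoformOverlaps: %s\n",
              object@excludeIsoformOverlaps))
})

setMethod("show", "Isoform", function(object) {
  cat(sprintf("Isoform %s [%s, %s strand] %d exon(s), %s\n",
              object@proteinId, object@targetId, object@strand,
              nrow(object@exons), object@completeness))
  if (length(object@issues))
    cat("  issues:", paste(object@issues, collapse = ", "), "\n")
})

setMethod("show", "GeneModel", function(object) {
  cat(sprintf("GeneModel %s [%s:%d-%d (%s)] %d isoform(s)\n",
              object@geneId, object@targetId, object@locusStart,
              object@locusEnd, object@strand, length(object@isoforms)))
})

setMethod("show", "MXECluster", function(object) {
  cat(sprintf("MXECluster %s [%s, %s] %d members, type %s\n",
              object@clusterId, object@geneId, object@targetId,
              nrow(object@members), object@type))
})

setMethod("show", "MXEResult", function(object) {
  cat(sprintf("MXEResult '%s': %d gene model(s), %d candidate(s), %d cluster(s)\n",
              object@dataset, length(object@geneModels),
              nrow(object@candidates), length(object@clusters)))
  cat(sprintf("  annotated MXE clusters: %d; constitutive MXE-like pairs: %d\n",
              length(object@annotatedClusters), nrow(object@constitutiveLike)))
})

setMethod("show", "PlantSpec", function(object) {
  cat(sprintf("PlantSpec: %d gene(s), %d planted cluster spec(s), seed %d\n",
              object@nGenes, nrow(object@plants), object@seed))
})
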