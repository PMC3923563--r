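#' Prediction parameter set
#'
#' Holds every tunable of the MXE search.  Two named presets exist (see
#' [predictionParams()]): the \emph{display} preset (minimum similarity score
#' 15\%, maximum length difference 20 aa, minimum original exon length 15 aa,
#' search restricted to the introns flanking the original exon, no flank
#' search) used for reported analyses, and the relaxed \emph{store} preset
#' (score 10\%, minimum exon length 10 aa, all introns plus 20,000 nt up- and
#' downstream) used by the prediction pipeline so that stored candidates can
#' later be re-filtered with stricter display values without re-running the
#' search.
#'
#' @slot minScore minimum similarity score in percent (may be negative;
#'   never exceeds 100 for identical peptides).
#' @slot maxLenDiff maximum length difference between original and candidate
#'   exon, in amino acids.
#' @slot minExonLen minimum length of the \emph{original} exon, in amino
#'   acids, for it to seed a search.
#' @slot scope \code{"flanking"} (only the introns surrounding the original
#'   exon) or \code{"all"} (every intron of the isoform).
#' @slot flankNt nucleotides of up-/downstream flank searched beyond the gene
#'   locus; 0 disables flank search.
#' @slot matrix name of the substitution matrix (a matrix shipped with
#'   \pkg{Biostrings}, default \code{"BLOSUM62"}).
#' @slot gapOpen,gapExtend affine gap penalties; a gap of length L costs
#'   \code{gapOpen + L * gapExtend}.
#' @slot minCandidateMargin minimum distance (nt) a candidate must keep from
#'   each edge of its search region.
#' @slot excludeIsoformOverlaps drop candidates overlapping (but not exactly
#'   matching) an exon of another isoform during filtering.
#' @seealso [predictionParams()]
#' @exportClass PredictionParams
setClass("PredictionParams", representation(
  minScore = "numeric", maxLenDiff = "numeric", minExonLen = "numeric",
  scope = "character", flankNt = "numeric", matrix = "character",
  gapOpen = "numeric", gapExtend = "numeric", minCandidateMargin = "numeric",
  excludeIsoformOverlaps = "logical"))

setValidity("PredictionParams", function(object) {
  msg <- character(0)
  if (length(object@minScore) != 1 || object@minScore > 100)
    msg <- c(msg, "minScore must be a single value <= 100")
  if (object@maxLenDiff < 0) msg <- c(msg, "maxLenDiff must be >= 0")
  if (object@minExonLen < 0) msg <- c(msg, "minExonLen must be >= 0")
  if (!object@scope %in% c("flanking", "all"))
    msg <- c(msg, "scope must be 'flanking' or 'all'")
  if (object@flankNt < 0) msg <- c(msg, "flankNt must be >= 0")
  if (object@gapOpen < 0 || object@gapExtend < 0)
    msg <- c(msg, "gap penalties must be >= 0")
  if (object@minCandidateMargin < 0)
    msg <- c(msg, "minCandidateMargin must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Create a prediction parameter set
#'
#' @param stage preset to start from: \code{"display"} (strict values used
#'   for reported analyses) or \code{"store"} (relaxed pipeline values so the
#'   stored candidate set can be re-filtered later).
#' @param minScore,maxLenDiff,minExonLen,scope,flankNt,matrix,gapOpen,
#'   gapExtend,minCandidateMargin,excludeIsoformOverlaps overrides of the
#'   preset; see [PredictionParams-class].
#' @return a [PredictionParams-class] object.
#' @examples
#' predictionParams()                  # display defaults
#' predictionParams("store")           # relaxed pipeline values
#' predictionParams(minScore = 25)     # stricter score threshold
#' @export
predictionParams <- function(stage = c("display", "store"),
                             minScore = NULL, maxLenDiff = NULL,
                             minExonLen = NULL, scope = NULL, flankNt = NULL,
                             matrix = "BLOSUM62", gapOpen = 11,
                             gapExtend = 1, minCandidateMargin = 20,
                             excludeIsoformOverlaps = TRUE) {
  stage <- match.arg(stage)
  preset <- if (stage == "display")
    list(minScore = 15, maxLenDiff = 20, minExonLen = 15,
         scope = "flanking", flankNt = 0)
  else
    list(minScore = 10, maxLenDiff = 20, minExonLen = 10,
         scope = "all", flankNt = 20000)
  new("PredictionParams",
      minScore = if (is.null(minScore)) preset$minScore else minScore,
      maxLenDiff = if (is.null(maxLenDiff)) preset$maxLenDiff else maxLenDiff,
      minExonLen = if (is.null(minExonLen)) preset$minExonLen else minExonLen,
      scope = if (is.null(scope)) preset$scope else scope,
      flankNt = if (is.null(flankNt)) preset$flankNt else flankNt,
      matrix = matrix, gapOpen = gapOpen, gapExtend = gapExtend,
      minCandidateMargin = minCandidateMargin,
      excludeIsoformOverlaps = excludeIsoformOverlaps)
}

#' Coding isoform
#'
#' One protein isoform of a gene: its ordered coding exons, the derived
#' introns, and the structural-validation verdict.  The \code{exons} slot is
#' a data.frame with one row per exon in transcription order and columns
#' \code{index}, \code{start}, \code{end} (0-based half-open, forward
#' strand), \code{startPhase} (nt to skip to reach the first complete codon),
#' \code{ntLen}, \code{aaLen} (\code{floor(ntLen/3)}), \code{peptide}
#' (translation of the exon's complete codons, used for scoring),
#' \code{displayPeptide} (junction codons attributed to the upstream exon, so
#' that concatenation reproduces the full CDS translation), \code{isInitial}
#' and \code{isTerminal}.
#'
#' @slot proteinId isoform/protein identifier.
#' @slot targetId contig the isoform lies on.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot exons exon table (see above).
#' @slot introns data.frame of derived intron intervals (\code{index},
#'   \code{start}, \code{end}) in transcription order.
#' @slot completeness \code{"complete"} or \code{"incomplete"}.
#' @slot issues character vector of structural issues (empty when complete).
#' @exportClass Isoform
setClass("Isoform", representation(
  proteinId = "character", targetId = "character", strand = "character",
  exons = "data.frame", introns = "data.frame", completeness = "character",
  issues = "character"))

setValidity("Isoform", function(object) {
  ex <- object@exons
  msg <- character(0)
  if (!nrow(ex)) msg <- c(msg, "isoform must have at least one exon")
  if (nrow(ex) && any(ex$ntLen < 1)) msg <- c(msg, "exon ntLen must be >= 1")
  if (nrow(object@introns) != max(0L, nrow(ex) - 1L))
    msg <- c(msg, "intron count must equal exon count - 1")
  if (nrow(ex) > 1) {
    o <- order(ex$start)
    so <- ex[o, ]
    if (any(so$start[-1] < so$end[-nrow(so)]))
      msg <- c(msg, "exons must be non-overlapping")
  }
  if (!object@completeness %in% c("complete", "incomplete"))
    msg <- c(msg, "completeness must be 'complete' or 'incomplete'")
  if (length(msg)) msg else TRUE
})

#' Gene model
#'
#' A coding gene: its locus, one or more [Isoform-class] objects, and the
#' exon intervals of the neighbouring genes on the same contig (used to flag
#' candidates that overlap a neighbour's exons).
#'
#' @slot geneId gene identifier.
#' @slot targetId contig identifier.
#' @slot strand \code{"+"} or \code{"-"}.
#' @slot locusStart,locusEnd 0-based half-open interval covering all isoform
#'   exons.
#' @slot isoforms list of [Isoform-class] objects.
#' @slot neighbourExons data.frame (\code{geneId}, \code{start}, \code{end})
#'   of exons of the adjacent genes on the same contig.
#' @exportClass GeneModel
setClass("GeneModel", representation(
  geneId = "character", targetId = "character", strand = "character",
  locusStart = "numeric", locusEnd = "numeric", isoforms = "list",
  neighbourExons = "data.frame"))

setValidity("GeneModel", function(object) {
  msg <- character(0)
  if (!length(object@isoforms)) msg <- c(msg, "gene must have >= 1 isoform")
  for (iso in object@isoforms) {
    if (!is(iso, "Isoform")) { msg <- c(msg, "isoforms must be Isoform objects"); break }
    if (nrow(iso@exons) &&
        (min(iso@exons$start) < object@locusStart ||
         max(iso@exons$end) > object@locusEnd)) {
      msg <- c(msg, "locus interval must cover all isoform exons"); break
    }
  }
  if (length(msg)) msg else TRUE
})

#' Cluster of mutually exclusive exons
#'
#' An ordered group of >= 2 neighbouring, non-overlapping exons (annotated
#' exons and/or surviving predicted candidates) occupying the same position
#' in the transcript, with a single type label.
#'
#' @slot clusterId identifier, unique within a result.
#' @slot geneId,targetId,strand gene context.
#' @slot type \code{"initial"}, \code{"internal"} or \code{"terminal"}.
#' @slot members data.frame with one row per member exon: \code{start},
#'   \code{end}, \code{provenance} (\code{annotated_mxe},
#'   \code{annotated_exon}, \code{predicted_new} or
#'   \code{constitutive_mxe_like}), \code{sourceExonIndex} (NA for annotated
#'   members) and \code{score} (NA for annotated members), ordered
#'   genomically.
#' @exportClass MXECluster
setClass("MXECluster", representation(
  clusterId = "character", geneId = "character", targetId = "character",
  strand = "character", type = "character", members = "data.frame"))

setValidity("MXECluster", function(object) {
  m <- object@members
  msg <- character(0)
  if (nrow(m) < 2) msg <- c(msg, "cluster must have >= 2 members")
  if (!object@type %in% c("initial", "internal", "terminal"))
    msg <- c(msg, "type must be initial|internal|terminal")
  if (nrow(m) > 1) {
    if (is.unsorted(m$start)) msg <- c(msg, "members must be ordered genomically")
    if (any(m$start[-1] < m$end[-nrow(m)]))
      msg <- c(msg, "members must be non-overlapping")
  }
  if (length(msg)) msg else TRUE
})

#' Result of an MXE prediction run
#'
#' The master container written to / read from the lossless YAML output:
#' the full (store-stage) candidate table, the clusters assembled from the
#' candidates surviving the run's filter parameters, annotated-MXE clusters
#' and MXE-like constitutive exon groups detected in the annotation, and the
#' dataset summary.  Re-filtering a result with stricter parameters
#' ([filterResult()]) never re-runs the search.
#'
#' @slot dataset dataset name.
#' @slot params the [PredictionParams-class] the run used.
#' @slot seed integer seed recorded for any randomized fixture generation
#'   (NA when none).
#' @slot targets data.frame (\code{id}, \code{length}) of target sequences.
#' @slot geneModels list of [GeneModel-class] (empty after YAML round-trip;
#'   models are rebuilt from the annotation, not serialized).
#' @slot candidates full candidate data.frame (see [predictGene()]).
#' @slot clusters list of [MXECluster-class] assembled from surviving
#'   candidates.
#' @slot annotatedClusters list of [MXECluster-class] detected from the
#'   annotation alone.
#' @slot constitutiveLike data.frame of neighbouring same-isoform exon pairs
#'   matching the MXE criteria.
#' @slot summary one-row data.frame of dataset counts (see
#'   [summarizeExome()]).
#' @exportClass MXEResult
setClass("MXEResult", representation(
  dataset = "character", params = "PredictionParams", seed = "numeric",
  targets = "data.frame", geneModels = "list", candidates = "data.frame",
  clusters = "list", annotatedClusters = "list",
  constitutiveLike = "data.frame", summary = "data.frame"))

#' Synthetic genome specification
#'
#' Describes a deterministic synthetic genome with planted MXE clusters.
#' See [plantSpec()] for defaults and [generatePlantedGenome()] for the
#' generator.
#'
#' @slot nGenes number of genes.
#' @slot exonsPerGene inclusive range of exon counts per gene.
#' @slot exonAaLen inclusive range of exon lengths in amino acids.
#' @slot intronLen inclusive range of intron lengths in nucleotides.
#' @slot intergenicNt intergenic spacer length in nucleotides.
#' @slot plants data.frame of planted alternatives: \code{gene} (1-based gene
#'   index), \code{exon} (source exon index), \code{nAlt} (number of
#'   alternatives), \code{identity} (target amino-acid identity in [0,1]),
#'   \code{lenOffset} (length offset in codons), \code{side}
#'   (\code{"upstream"}, \code{"downstream"} or \code{"both"}).
#' @slot isoformPattern per-gene annotation pattern: \code{"single"},
#'   \code{"annotated_mxe"} (second isoform using an alternative exon) or
#'   \code{"cassette"} (second isoform including both exons).
#' @slot patternIdentity per-gene amino-acid identity of the pattern
#'   alternative exon (recycled; ignored for \code{"single"} genes).
#' @slot gcDonorProb probability that an intron uses a GC donor.
#' @slot flankDup plant an ordered copy of two exons downstream of each gene
#'   (tandem-duplication signature).
#' @slot minusStrandProb probability a gene is placed on the minus strand.
#' @slot seed integer; fully determines the output.
#' @exportClass PlantSpec
setClass("PlantSpec", representation(
  nGenes = "integer", exonsPerGene = "integer", exonAaLen = "integer",
  intronLen = "integer", intergenicNt = "integer", plants = "data.frame",
  isoformPattern = "character", patternIdentity = "numeric",
  gcDonorProb = "numeric", flankDup = "logical", minusStrandProb = "numeric",
  seed = "integer"))

setValidity("PlantSpec", function(object) {
  msg <- character(0)
  if (object@nGenes < 0) msg <- c(msg, "nGenes must be >= 0")
  if (nrow(object@plants)) {
    if (any(object@plants$identity < 0 | object@plants$identity > 1))
      msg <- c(msg, "plant identity must be in [0,1]")
    if (any(object@plants$gene < 1 | object@plants$gene > object@nGenes))
      msg <- c(msg, "plant gene index out of range")
  }
  if (length(object@isoformPattern) != object@nGenes)
    msg <- c(msg, "isoformPattern must have one entry per gene")
  if (!all(object@isoformPattern %in% c("single", "annotated_mxe", "cassette")))
    msg <- c(msg, "unknown isoform pattern")
  if (any(object@patternIdentity < 0 | object@patternIdentity > 1))
    msg <- c(msg, "patternIdentity must be in [0,1]")
  if (length(msg)) msg else TRUE
})
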