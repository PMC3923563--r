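# Reading genomes and GFF3 annotations; writing results as YAML (lossless
# master), TSV, GFF3 and BED.  GFF3 is 1-based inclusive, BED and the internal
# convention are 0-based half-open.

#' Read a genome FASTA file
#'
#' Reads one record per contig/chromosome.  Record ids are the first
#' whitespace-delimited token of the header, sequences are uppercased and
#' \code{U} is mapped to \code{T}.
#'
#' @param path path to a FASTA file.
#' @return a [Biostrings::DNAStringSet] named by contig id.
#' @examples
#' f <- tempfile(fileext = ".fasta")
#' writeLines(c(">chr1 description", "acgt"), f)
#' readGenome(f)
#' @export
readGenome <- function(path) {
  if (!file.exists(path)) stop("genome FASTA not found: ", path)
  if (file.size(path) == 0L) {
    warning("empty FASTA file: ", path)
    return(DNAStringSet())
  }
  raw <- tryCatch(readBStringSet(path),
                  error = function(e)
                    stop("malformed FASTA '", path, "': ",
                         conditionMessage(e), call. = FALSE))
  ids <- sub("\\s.*$", "", names(raw))
  if (anyDuplicated(ids))
    stop("duplicate sequence ids in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  seqs <- chartr("u", "T", chartr("U", "T", toupper(as.character(raw))))
  bad <- grepl("[^ACGTN]", seqs)
  if (any(bad))
    stop("sequence(s) with characters outside A,C,G,T,N,U: ",
         paste(ids[bad], collapse = ", "))
  out <- DNAStringSet(seqs)
  names(out) <- ids
  out
}

#' Write a genome FASTA file
#'
#' @param genome a named [Biostrings::DNAStringSet].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeGenome <- function(genome, path) {
  writeXStringSet(genome, path)
  invisible(path)
}

#' Read a coding-gene GFF3 annotation
#'
#' Parses gene / mRNA (or transcript) / CDS rows into a flat table of CDS
#' segments grouped per isoform and sorted in transcription order (descending
#' genomic order on the minus strand).  GFF3 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention; the CDS phase
#' column is preserved (NA when absent).
#'
#' @param path path to a GFF3 file.
#' @param genome the genome the annotation refers to (a
#'   [Biostrings::DNAStringSet]); used to validate contig ids and bounds.
#' @return a data.frame with columns \code{geneId}, \code{proteinId},
#'   \code{targetId}, \code{start}, \code{end}, \code{strand}, \code{phase}.
#' @export
readAnnotation <- function(path, genome) {
  if (!file.exists(path)) stop("annotation GFF3 not found: ", path)
  gr <- tryCatch(rtracklayer::import(path, format = "gff3"),
                 error = function(e)
                   stop("malformed GFF3 '", path, "': ",
                        conditionMessage(e), call. = FALSE))
  md <- S4Vectors::mcols(gr)
  type <- as.character(md$type)
  ids <- if ("ID" %in% colnames(md)) as.character(md$ID) else
    rep(NA_character_, length(gr))
  parents <- if ("Parent" %in% colnames(md)) md$Parent else
    rep(list(character(0)), length(gr))

  isTx <- type %in% c("mRNA", "transcript")
  txId <- ids[isTx]
  txParent <- vapply(parents[isTx], function(p)
    if (length(p)) p[[1]] else NA_character_, character(1))
  txGene <- stats::setNames(txParent, txId)

  isCDS <- type == "CDS"
  if (!any(isCDS)) {
    warning("no CDS features in ", path)
    return(data.frame(geneId = character(0), proteinId = character(0),
                      targetId = character(0), start = numeric(0),
                      end = numeric(0), strand = character(0),
                      phase = integer(0), stringsAsFactors = FALSE))
  }
  cds <- gr[isCDS]
  cdsParents <- parents[isCDS]
  nPar <- lengths(cdsParents)
  if (any(nPar == 0L)) {
    warning(sum(nPar == 0L), " CDS record(s) without Parent skipped")
    cds <- cds[nPar > 0L]
    cdsParents <- cdsParents[nPar > 0L]
    nPar <- nPar[nPar > 0L]
  }
  # a CDS row may belong to several isoforms; replicate per parent
  rep_idx <- rep(seq_along(cds), nPar)
  tx <- unlist(cdsParents, use.names = FALSE)
  df <- data.frame(
    proteinId = tx,
    targetId = as.character(GenomicRanges::seqnames(cds))[rep_idx],
    start = GenomicRanges::start(cds)[rep_idx] - 1,
    end = as.numeric(GenomicRanges::end(cds))[rep_idx],
    strand = as.character(GenomicRanges::strand(cds))[rep_idx],
    phase = as.integer(S4Vectors::mcols(cds)$phase)[rep_idx],
    stringsAsFactors = FALSE)

  unknownTx <- !df$proteinId %in% names(txGene)
  if (any(unknownTx)) {
    warning(sum(unknownTx),
            " CDS record(s) referencing unknown transcripts skipped")
    df <- df[!unknownTx, , drop = FALSE]
  }
  if (!nrow(df)) stop("no usable CDS records in ", path)
  df$geneId <- unname(txGene[df$proteinId])
  df$geneId[is.na(df$geneId)] <- df$proteinId[is.na(df$geneId)]

  badTarget <- !df$targetId %in% names(genome)
  if (any(badTarget))
    stop("CDS on unknown contig(s): ",
         paste(unique(df$targetId[badTarget]), collapse = ", "))
  lens <- width(genome)[match(df$targetId, names(genome))]
  if (any(df$start < 0 | df$end > lens))
    stop("CDS coordinates outside contig bounds in ", path)

  # transcription order within each isoform
  ord <- order(df$geneId, df$proteinId,
               ifelse(df$strand == "-", -df$start, df$start))
  df <- df[ord, c("geneId", "proteinId", "targetId", "start", "end",
                  "strand", "phase")]
  rownames(df) <- NULL
  df
}

#' Write an annotation table as GFF3
#'
#' Inverse of [readAnnotation()]: writes gene, mRNA and CDS rows with
#' 1-based inclusive coordinates.
#'
#' @param ann annotation data.frame as returned by [readAnnotation()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeAnnotationGFF3 <- function(ann, path) {
  lines <- "##gff-version 3"
  for (g in unique(ann$geneId)) {
    ga <- ann[ann$geneId == g, , drop = FALSE]
    gl <- sprintf("%s\tmxefinder\tgene\t%d\t%d\t.\t%s\t.\tID=%s",
                  ga$targetId[1], min(ga$start) + 1L, max(ga$end),
                  ga$strand[1], g)
    lines <- c(lines, gl)
    for (tx in unique(ga$proteinId)) {
      ta <- ga[ga$proteinId == tx, , drop = FALSE]
      lines <- c(lines, sprintf(
        "%s\tmxefinder\tmRNA\t%d\t%d\t.\t%s\t.\tID=%s;Parent=%s",
        ta$targetId[1], min(ta$start) + 1L, max(ta$end), ta$strand[1], tx, g))
      ph <- ifelse(is.na(ta$phase), ".", as.character(ta$phase))
      lines <- c(lines, sprintf(
        "%s\tmxefinder\tCDS\t%d\t%d\t.\t%s\t%s\tID=%s.cds%d;Parent=%s",
        ta$targetId, ta$start + 1L, ta$end, ta$strand, ph, tx,
        seq_len(nrow(ta)), tx))
    }
  }
  writeLines(lines, path)
  invisible(path)
}

.clusterToList <- function(cl) {
  list(clusterId = cl@clusterId, geneId = cl@geneId, targetId = cl@targetId,
       strand = cl@strand, type = cl@type,
       members = lapply(seq_len(nrow(cl@members)), function(i)
         as.list(cl@members[i, , drop = FALSE])))
}

.clusterFromList <- function(x) {
  mem <- do.call(rbind, lapply(x$members, function(m)
    data.frame(start = as.numeric(m$start), end = as.numeric(m$end),
               provenance = m$provenance,
               sourceExonIndex = if (is.null(m$sourceExonIndex) ||
                                     is.na(m$sourceExonIndex)) NA_integer_
                                 else as.integer(m$sourceExonIndex),
               score = if (is.null(m$score) || is.na(m$score)) NA_real_
                       else as.numeric(m$score),
               stringsAsFactors = FALSE)))
  new("MXECluster", clusterId = x$clusterId, geneId = x$geneId,
      targetId = x$targetId, strand = x$strand, type = x$type, members = mem)
}

.paramsToList <- function(p) {
  list(minScore = p@minScore, maxLenDiff = p@maxLenDiff,
       minExonLen = p@minExonLen, scope = p@scope, flankNt = p@flankNt,
       matrix = p@matrix, gapOpen = p@gapOpen, gapExtend = p@gapExtend,
       minCandidateMargin = p@minCandidateMargin,
       excludeIsoformOverlaps = p@excludeIsoformOverlaps)
}

.paramsFromList <- function(x) {
  new("PredictionParams", minScore = x$minScore, maxLenDiff = x$maxLenDiff,
      minExonLen = x$minExonLen, scope = x$scope, flankNt = x$flankNt,
      matrix = x$matrix, gapOpen = x$gapOpen, gapExtend = x$gapExtend,
      minCandidateMargin = x$minCandidateMargin,
      excludeIsoformOverlaps = x$excludeIsoformOverlaps)
}

# data.frame <-> list-of-rows with type template for lossless YAML round-trip
.dfToRows <- function(df) lapply(seq_len(nrow(df)), function(i) {
  r <- as.list(df[i, , drop = FALSE])
  lapply(r, function(v) if (is.factor(v)) as.character(v) else v)
})

.rowsToDf <- function(rows, template) {
  if (!length(rows)) return(template)
  cols <- names(template)
  out <- lapply(cols, function(cn) {
    unlist(lapply(rows, function(r) {
      x <- r[[cn]]
      if (is.null(x) || (length(x) == 1L && is.na(x))) NA else x
    }), use.names = FALSE)
  })
  names(out) <- cols
  df <- as.data.frame(out, stringsAsFactors = FALSE)
  for (cn in cols) {
    df[[cn]] <- switch(class(template[[cn]])[1],
                       integer = as.integer(df[[cn]]),
                       numeric = as.numeric(df[[cn]]),
                       logical = as.logical(df[[cn]]),
                       character = as.character(df[[cn]]),
                       df[[cn]])
  }
  df
}

.emptyConstitutiveLike <- function() {
  data.frame(geneId = character(0), proteinId = character(0),
             groupId = character(0), exonIndexA = integer(0),
             exonIndexB = integer(0), startA = numeric(0), endA = numeric(0),
             startB = numeric(0), endB = numeric(0), lenDiffAa = integer(0),
             score = numeric(0), stringsAsFactors = FALSE)
}

#' Write the lossless YAML master output
#'
#' The YAML file is self-describing: it carries the parameters used, the
#' target table, every candidate field, all clusters and the summary, at full
#' numeric precision, so that the filter stage can be re-run from the YAML
#' alone and reproduce the filtered set bit-identically.
#'
#' @param result an [MXEResult-class].
#' @param path output path.
#' @return the path, invisibly.
#' @seealso [readResultsYAML()]
#' @export
writeResultsYAML <- function(result, path) {
  doc <- list(
    schema = "mxefinder-results",
    schema_version = 1L,
    dataset = result@dataset,
    seed = if (is.na(result@seed)) NULL else result@seed,
    params = .paramsToList(result@params),
    targets = .dfToRows(result@targets),
    candidates = .dfToRows(result@candidates),
    clusters = lapply(result@clusters, .clusterToList),
    annotated_clusters = lapply(result@annotatedClusters, .clusterToList),
    constitutive_like = .dfToRows(result@constitutiveLike),
    summary = if (nrow(result@summary)) as.list(result@summary[1, ]) else list())
  writeLines(as.yaml(doc, precision = 17L), path)
  invisible(path)
}

#' Read an MXE result from its YAML master output
#'
#' @param path a YAML file written by [writeResultsYAML()].
#' @return an [MXEResult-class] (gene models are not serialized and come back
#'   empty).
#' @export
readResultsYAML <- function(path) {
  doc <- yaml::read_yaml(path)
  if (is.null(doc$schema) || doc$schema != "mxefinder-results")
    stop("not an mxefinder results file: ", path)
  summ <- if (length(doc$summary))
    as.data.frame(doc$summary, stringsAsFactors = FALSE) else data.frame()
  new("MXEResult",
      dataset = doc$dataset,
      params = .paramsFromList(doc$params),
      seed = if (is.null(doc$seed)) NA_real_ else as.numeric(doc$seed),
      targets = .rowsToDf(doc$targets,
                          data.frame(id = character(0), length = numeric(0),
                                     stringsAsFactors = FALSE)),
      geneModels = list(),
      candidates = .rowsToDf(doc$candidates, .emptyCandidates()),
      clusters = lapply(doc$clusters, .clusterFromList),
      annotatedClusters = lapply(doc$annotated_clusters, .clusterFromList),
      constitutiveLike = .rowsToDf(doc$constitutive_like,
                                   .emptyConstitutiveLike()),
      summary = summ)
}

#' Write candidates as TSV
#'
#' One candidate per row; headers-only when the candidate set is empty.
#'
#' @param candidates candidate data.frame (or an [MXEResult-class]).
#' @param path output path.
#' @return the path, invisibly.
#' @export
writeCandidatesTSV <- function(candidates, path) {
  if (is(candidates, "MXEResult")) candidates <- candidates@candidates
  write.table(candidates, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write candidates as GFF3
#'
#' Candidate coordinates are converted to the 1-based inclusive GFF3
#' convention; the score column carries the similarity score in percent.
#' Cluster membership, when clusters are supplied, is written as
#' \code{cluster_id} and \code{cluster_type} attributes.
#'
#' @param candidates candidate data.frame (or an [MXEResult-class], whose
#'   clusters are then used).
#' @param path output path.
#' @param clusters optional list of [MXECluster-class].
#' @return the path, invisibly.
#' @export
writeCandidatesGFF3 <- function(candidates, path, clusters = list()) {
  if (is(candidates, "MXEResult")) {
    clusters <- candidates@clusters
    candidates <- candidates@candidates
  }
  lines <- "##gff-version 3"
  clusOf <- character(0)
  typeOf <- character(0)
  for (cl in clusters) {
    key <- paste(cl@geneId, cl@members$start, cl@members$end, sep = "|")
    clusOf[key] <- cl@clusterId
    typeOf[key] <- cl@type
  }
  if (nrow(candidates)) {
    key <- paste(candidates$geneId, candidates$start, candidates$end, sep = "|")
    attr1 <- sprintf("ID=%s;gene_id=%s;source_exon=%d;location=%s",
                     candidates$candidateId, candidates$geneId,
                     candidates$sourceExonIndex, candidates$location)
    inClus <- key %in% names(clusOf)
    attr1[inClus] <- paste0(attr1[inClus], ";cluster_id=",
                            clusOf[key[inClus]], ";cluster_type=",
                            typeOf[key[inClus]])
    lines <- c(lines, sprintf(
      "%s\tmxefinder\texon\t%d\t%d\t%s\t%s\t.\t%s",
      candidates$targetId, as.integer(candidates$start) + 1L,
      as.integer(candidates$end),
      formatC(candidates$score, format = "f", digits = 3),
      candidates$strand, attr1))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Write candidates as BED6
#'
#' BED is 0-based half-open; the score column carries the similarity score in
#' percent and the name column the candidate id.
#'
#' @inheritParams writeCandidatesTSV
#' @return the path, invisibly.
#' @export
writeCandidatesBED <- function(candidates, path) {
  if (is(candidates, "MXEResult")) candidates <- candidates@candidates
  if (!nrow(candidates)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  lines <- sprintf("%s\t%d\t%d\t%s\t%s\t%s",
                   candidates$targetId, as.integer(candidates$start),
                   as.integer(candidates$end), candidates$candidateId,
                   formatC(candidates$score, format = "f", digits = 3),
                   candidates$strand)
  writeLines(lines, path)
  invisible(path)
}

#' Write prediction results in one or more formats
#'
#' @param result an [MXEResult-class].
#' @param dir output directory (created if missing).
#' @param formats subset of \code{"yaml"}, \code{"tsv"}, \code{"gff3"},
#'   \code{"bed"}.
#' @param prefix file name prefix; defaults to the dataset name.
#' @return named character vector of written paths, invisibly.
#' @export
writeResults <- function(result, dir,
                         formats = c("yaml", "tsv", "gff3", "bed"),
                         prefix = result@dataset) {
  supported <- c("yaml", "tsv", "gff3", "bed")
  bad <- setdiff(formats, supported)
  if (length(bad))
    stop("unknown format(s): ", paste(bad, collapse = ", "),
         "; supported: ", paste(supported, collapse = ", "))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- character(0)
  for (fmt in formats) {
    p <- file.path(dir, paste0(prefix, ".", fmt))
    switch(fmt,
           yaml = writeResultsYAML(result, p),
           tsv = writeCandidatesTSV(result, p),
           gff3 = writeCandidatesGFF3(result, p),
           bed = writeCandidatesBED(result, p))
    paths[fmt] <- p
  }
  invisible(paths)
}
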