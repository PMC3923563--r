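# Filter algebra, isoform/neighbour reconciliation, annotated-MXE detection,
# cluster assembly and classification, tandem/trans-splicing signature.

#' Apply the display filters to a candidate set
#'
#' Pure filtering: each rule is a predicate on stored candidate fields, so
#' re-filtering a stored (relaxed) prediction is supported without
#' re-running the search.  Rules, in report order: similarity score >=
#' \code{minScore}; length difference <= \code{maxLenDiff}; original exon
#' length >= \code{minExonLen}; location class permitted by the scope
#' (flanking introns only, or all introns; flank candidates only when
#' \code{flankNt} > 0 and within the window); candidates overlapping (but not
#' exactly matching) an exon of another isoform dropped when
#' \code{excludeIsoformOverlaps} is set.
#'
#' @param candidates candidate data.frame or an [MXEResult-class].
#' @param params a [PredictionParams-class].
#' @return list with \code{candidates} (surviving rows) and \code{report}
#'   (data.frame \code{candidateId}, \code{pass}, \code{firstFail}; every
#'   input candidate appears exactly once).
#' @export
applyFilters <- function(candidates, params) {
  if (is(candidates, "MXEResult")) candidates <- candidates@candidates
  df <- candidates
  n <- nrow(df)
  if (!n)
    return(list(candidates = df,
                report = data.frame(candidateId = character(0),
                                    pass = logical(0),
                                    firstFail = character(0),
                                    stringsAsFactors = FALSE)))
  failScore <- df$score < params@minScore
  failLen <- df$lenDiffAa > params@maxLenDiff
  failExon <- df$sourceAaLen < params@minExonLen
  allowedIntrons <- if (params@scope == "all")
    c("upstream_intron", "other_intron", "downstream_intron")
  else c("upstream_intron", "downstream_intron")
  isFlank <- df$location %in% c("upstream_flank", "downstream_flank")
  failScope <- !(df$location %in% allowedIntrons |
                   (isFlank & params@flankNt > 0 &
                      !is.na(df$flankDistNt) &
                      df$flankDistNt <= params@flankNt))
  failOverlap <- if (params@excludeIsoformOverlaps)
    df$flagIsoformOverlap & !df$flagExactMatch else rep(FALSE, n)

  firstFail <- rep(NA_character_, n)
  firstFail[failOverlap] <- "overlap"
  firstFail[failScope] <- "scope"
  firstFail[failExon] <- "min_exon_len"
  firstFail[failLen] <- "length_diff"
  firstFail[failScore] <- "score"
  pass <- is.na(firstFail)
  list(candidates = df[pass, , drop = FALSE],
       report = data.frame(candidateId = df$candidateId, pass = pass,
                           firstFail = firstFail, stringsAsFactors = FALSE))
}

#' Reconcile candidates across isoforms and neighbouring genes
#'
#' A candidate whose interval exactly matches an exon of another isoform of
#' the same gene gets the exact-match flag (confirmation); one that overlaps
#' but does not match gets the overlap flag (potential false positive,
#' deselectable in filtering); one overlapping any exon of a neighbouring
#' gene gets the neighbour flag.
#'
#' @param gene the [GeneModel-class] the candidates belong to.
#' @param candidates candidate rows of this gene.
#' @return the candidates with the three flags set.
#' @export
reconcileIsoforms <- function(gene, candidates) {
  if (!nrow(candidates)) return(candidates)
  exonsByIso <- lapply(gene@isoforms, function(i)
    i@exons[, c("start", "end")])
  names(exonsByIso) <- vapply(gene@isoforms, slot, character(1), "proteinId")
  nb <- gene@neighbourExons
  for (i in seq_len(nrow(candidates))) {
    own <- candidates$proteinId[i]
    others <- exonsByIso[names(exonsByIso) != own]
    if (length(others)) {
      oth <- do.call(rbind, others)
      exact <- any(oth$start == candidates$start[i] &
                     oth$end == candidates$end[i])
      over <- any(.overlaps(candidates$start[i], candidates$end[i],
                            oth$start, oth$end) &
                    !(oth$start == candidates$start[i] &
                        oth$end == candidates$end[i]))
      candidates$flagExactMatch[i] <- exact
      candidates$flagIsoformOverlap[i] <- over
    }
    if (nrow(nb))
      candidates$flagNeighbourOverlap[i] <-
        any(.overlaps(candidates$start[i], candidates$end[i],
                      nb$start, nb$end))
  }
  candidates
}

#' Detect clusters of annotated mutually exclusive exons
#'
#' An annotated MXE cluster is a maximal group of two or more neighbouring,
#' mutually non-overlapping exons such that every annotated isoform of the
#' gene includes exactly and only one member of the group.  An isoform
#' containing two members (cassette pattern) or none disqualifies the group.
#' "Neighbouring" means no annotated exon of any isoform lies strictly
#' between group members.
#'
#' @param gene a [GeneModel-class].
#' @return list of [MXECluster-class] with member provenance
#'   \code{annotated_mxe} (empty for single-isoform genes).
#' @export
detectAnnotatedMXEClusters <- function(gene) {
  if (length(gene@isoforms) < 2) return(list())
  exAll <- do.call(rbind, lapply(gene@isoforms, function(i)
    data.frame(proteinId = i@proteinId, start = i@exons$start,
               end = i@exons$end, stringsAsFactors = FALSE)))
  distinct <- unique(exAll[, c("start", "end")])
  distinct <- distinct[order(distinct$start, distinct$end), , drop = FALSE]
  nd <- nrow(distinct)
  if (nd < 2) return(list())
  isoKeys <- lapply(gene@isoforms, function(i)
    paste(i@exons$start, i@exons$end))
  dKey <- paste(distinct$start, distinct$end)

  valid <- list()
  for (i in seq_len(nd - 1L)) {
    for (j in seq(i + 1L, nd)) {
      mem <- distinct[i:j, , drop = FALSE]
      if (any(mem$start[-1] < mem$end[-nrow(mem)])) next  # overlap
      counts <- vapply(isoKeys, function(k) sum(k %in% dKey[i:j]), integer(1))
      if (all(counts == 1L)) valid[[length(valid) + 1L]] <- c(i, j)
    }
  }
  if (!length(valid)) return(list())
  # keep maximal windows only
  keep <- vapply(seq_along(valid), function(a) {
    va <- valid[[a]]
    !any(vapply(seq_along(valid), function(b) {
      if (a == b) return(FALSE)
      vb <- valid[[b]]
      vb[1] <= va[1] && vb[2] >= va[2]
    }, logical(1)))
  }, logical(1))
  valid <- valid[keep]

  lapply(seq_along(valid), function(k) {
    ij <- valid[[k]]
    mem <- distinct[ij[1]:ij[2], , drop = FALSE]
    members <- data.frame(start = mem$start, end = mem$end,
                          provenance = "annotated_mxe",
                          sourceExonIndex = NA_integer_, score = NA_real_,
                          stringsAsFactors = FALSE)
    cl <- new("MXECluster",
              clusterId = paste0(gene@geneId, ":amxe", k),
              geneId = gene@geneId, targetId = gene@targetId,
              strand = gene@strand, type = "internal", members = members)
    cl@type <- classifyCluster(cl, gene)
    cl
  })
}

#' Detect constitutive exons matching the MXE criteria
#'
#' Flags neighbouring exons within one isoform that pairwise satisfy the MXE
#' criteria: frame-compatible lengths, length difference within the bound,
#' both exons at least \code{minExonLen} amino acids, and similarity score at
#' least \code{minScore} (the score is computed in both directions and the
#' better one is used).  Chains of qualifying adjacent pairs are merged into
#' groups.
#'
#' @param gene a [GeneModel-class].
#' @param params a [PredictionParams-class].
#' @return data.frame of qualifying pairs with a \code{groupId} column
#'   (zero rows when none qualify).
#' @export
detectConstitutiveMXELike <- function(gene, params = predictionParams()) {
  out <- .emptyConstitutiveLike()
  for (iso in gene@isoforms) {
    ex <- iso@exons
    if (nrow(ex) < 2) next
    grp <- 0L
    lastQualified <- FALSE
    for (i in seq_len(nrow(ex) - 1L)) {
      a <- ex[i, ]; b <- ex[i + 1L, ]
      qual <- FALSE
      if (!is.na(a$peptide) && !is.na(b$peptide) &&
          nzchar(a$peptide) && nzchar(b$peptide) &&
          frameCompatible(a$ntLen, b$ntLen) &&
          abs(a$ntLen - b$ntLen) %/% 3L <= params@maxLenDiff &&
          a$aaLen >= params@minExonLen && b$aaLen >= params@minExonLen) {
        sc <- max(similarityScore(a$peptide, b$peptide, params),
                  similarityScore(b$peptide, a$peptide, params))
        if (sc >= params@minScore) {
          qual <- TRUE
          if (!lastQualified) grp <- grp + 1L
          out <- rbind(out, data.frame(
            geneId = gene@geneId, proteinId = iso@proteinId,
            groupId = paste0(gene@geneId, ":", iso@proteinId, ":cml", grp),
            exonIndexA = a$index, exonIndexB = b$index,
            startA = a$start, endA = a$end, startB = b$start, endB = b$end,
            lenDiffAa = abs(a$ntLen - b$ntLen) %/% 3L, score = sc,
            stringsAsFactors = FALSE))
        }
      }
      lastQualified <- qual
    }
  }
  rownames(out) <- NULL
  out
}

#' Assemble MXE clusters from surviving candidates
#'
#' Each source exon together with its surviving candidates forms a cluster;
#' clusters sharing a member interval, or whose source exons mutually
#' predict each other, are merged (transitive closure).  Duplicate member
#' intervals are collapsed (annotated provenance wins); members that overlap
#' without being identical are resolved by dropping the lower-scoring
#' candidate with a warning.  Members are ordered genomically and the
#' cluster is classified with [classifyCluster()].
#'
#' @param gene a [GeneModel-class].
#' @param surviving candidate rows of this gene that passed [applyFilters()].
#' @return list of [MXECluster-class].
#' @export
assembleClusters <- function(gene, surviving) {
  if (!nrow(surviving)) return(list())
  srcKey <- paste(surviving$sourceExonStart, surviving$sourceExonEnd)
  sources <- unique(data.frame(start = surviving$sourceExonStart,
                               end = surviving$sourceExonEnd,
                               key = srcKey, stringsAsFactors = FALSE))
  ns <- nrow(sources)
  parent <- seq_len(ns)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  union2 <- function(i, j) {
    ri <- find(i); rj <- find(j)
    if (ri != rj) parent[max(ri, rj)] <<- min(ri, rj)
  }

  candKeysOf <- lapply(sources$key, function(k)
    paste(surviving$start[srcKey == k], surviving$end[srcKey == k]))
  memberKeysOf <- lapply(seq_len(ns), function(i)
    c(sources$key[i], candKeysOf[[i]]))
  for (i in seq_len(ns)) {
    for (j in seq_len(ns)) {
      if (j <= i) next
      if (length(intersect(memberKeysOf[[i]], memberKeysOf[[j]])) > 0 ||
          (sources$key[j] %in% candKeysOf[[i]] &&
             sources$key[i] %in% candKeysOf[[j]]))
        union2(i, j)
    }
  }
  roots <- vapply(seq_len(ns), find, integer(1))

  annotatedKeys <- unique(unlist(lapply(gene@isoforms, function(i)
    paste(i@exons$start, i@exons$end))))

  clusters <- list()
  for (r in unique(roots)) {
    idx <- which(roots == r)
    rows <- surviving[srcKey %in% sources$key[idx], , drop = FALSE]
    members <- rbind(
      data.frame(start = sources$start[idx], end = sources$end[idx],
                 provenance = "annotated_exon",
                 sourceExonIndex = NA_integer_, score = NA_real_,
                 stringsAsFactors = FALSE),
      data.frame(start = rows$start, end = rows$end,
                 provenance = ifelse(paste(rows$start, rows$end) %in%
                                       annotatedKeys,
                                     "annotated_exon", "predicted_new"),
                 sourceExonIndex = rows$sourceExonIndex, score = rows$score,
                 stringsAsFactors = FALSE))
    # collapse duplicate intervals; annotated provenance and best score win
    members <- members[order(members$start, members$end,
                             members$provenance != "annotated_exon",
                             -ifelse(is.na(members$score), Inf,
                                     members$score)), , drop = FALSE]
    members <- members[!duplicated(paste(members$start, members$end)), ,
                       drop = FALSE]
    # resolve overlapping-but-not-identical members
    repeat {
      drop <- NA
      for (i in seq_len(nrow(members) - 1L)) {
        if (members$start[i + 1L] < members$end[i]) {
          si <- ifelse(is.na(members$score[i]), Inf, members$score[i])
          sj <- ifelse(is.na(members$score[i + 1L]), Inf,
                       members$score[i + 1L])
          drop <- if (si < sj) i else i + 1L
          break
        }
      }
      if (is.na(drop)) break
      warning("overlapping cluster members in gene ", gene@geneId,
              "; dropping the lower-scoring candidate")
      members <- members[-drop, , drop = FALSE]
    }
    if (nrow(members) < 2) next
    rownames(members) <- NULL
    cl <- new("MXECluster",
              clusterId = paste0(gene@geneId, ":cl", length(clusters) + 1L),
              geneId = gene@geneId, targetId = gene@targetId,
              strand = gene@strand, type = "internal", members = members)
    cl@type <- classifyCluster(cl, gene)
    clusters[[length(clusters) + 1L]] <- cl
  }
  clusters
}

#' Classify a cluster as initial, internal or terminal
#'
#' A cluster containing any isoform's first coding exon is \code{initial}
#' (alternative transcription starts / multiple promoters); one containing
#' any isoform's last coding exon is \code{terminal} (multiple poly(A)
#' sites); anything else is \code{internal}.  A cluster qualifying as both
#' (two-exon isoforms) is labelled initial; the tie-break is logged.
#'
#' @param cluster an [MXECluster-class].
#' @param gene the [GeneModel-class] it belongs to.
#' @return one of \code{"initial"}, \code{"internal"}, \code{"terminal"}.
#' @export
classifyCluster <- function(cluster, gene) {
  memKey <- paste(cluster@members$start, cluster@members$end)
  firstKeys <- vapply(gene@isoforms, function(i)
    paste(i@exons$start[1], i@exons$end[1]), character(1))
  lastKeys <- vapply(gene@isoforms, function(i) {
    n <- nrow(i@exons); paste(i@exons$start[n], i@exons$end[n])
  }, character(1))
  isInitial <- any(memKey %in% firstKeys)
  isTerminal <- any(memKey %in% lastKeys)
  if (isInitial && isTerminal) {
    message("cluster ", cluster@clusterId,
            " qualifies as both initial and terminal; labelled initial")
    return("initial")
  }
  if (isInitial) return("initial")
  if (isTerminal) return("terminal")
  "internal"
}

#' Flag tandem-duplication / trans-splicing signatures
#'
#' Ordered copies of several of a gene's exons in its up- or downstream
#' flank indicate a tandem gene duplicate or a trans-spliced gene rather
#' than mutually exclusive splicing.  The flag is raised iff at least two
#' distinct source exons each have a flank candidate on the same side with
#' their genomic order preserved relative to the source exons.
#'
#' @param gene a [GeneModel-class].
#' @param candidates candidate rows of this gene (prediction must have run
#'   with \code{flankNt} > 0 for flank candidates to exist).
#' @return list with \code{flag} (logical) and \code{supporting} (the
#'   candidate rows witnessing the pattern; zero rows when flag is FALSE).
#' @export
flagTandemOrTrans <- function(gene, candidates) {
  fl <- candidates[candidates$geneId == gene@geneId &
                     candidates$location %in% c("upstream_flank",
                                                "downstream_flank"), ,
                   drop = FALSE]
  if (!nrow(fl)) return(list(flag = FALSE, supporting = fl))
  # transcription-orientation position: ascending along the mRNA
  txPos <- if (gene@strand == "-") -fl$start else fl$start
  support <- integer(0)
  for (side in c("upstream_flank", "downstream_flank")) {
    s <- which(fl$location == side)
    if (length(unique(fl$sourceExonIndex[s])) < 2) next
    for (i in s) for (j in s) {
      if (fl$sourceExonIndex[i] < fl$sourceExonIndex[j] &&
          txPos[i] < txPos[j])
        support <- union(support, c(i, j))
    }
  }
  list(flag = length(support) > 0,
       supporting = fl[sort(support), , drop = FALSE])
}
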