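# A deterministic three-exon worked-example gene carrying a cluster of four
# mutually exclusive exons, engineered so that each display filter removes a
# known subset of the planted candidates.

# deterministically degrade a peptide by single substitutions until its
# similarity score against the original falls into [low, high): greedy
# descent that takes a substitution landing in the band if one exists,
# otherwise the smallest step that stays above the band
.degradeToScoreBand <- function(pep, low, high, params) {
  aas <- .aaLetters()
  cur <- pep
  for (iter in seq_len(4L * nchar(pep))) {
    chars <- strsplit(cur, "")[[1]]
    cands <- character(0)
    for (p in seq_along(chars)) {
      for (a in aas) {
        if (a == chars[p]) next
        x <- chars
        x[p] <- a
        cands <- c(cands, paste(x, collapse = ""))
      }
    }
    scs <- .scoreMany(pep, cands, params)
    inBand <- scs >= low & scs < high
    if (any(inBand)) {
      idx <- which(inBand)
      return(cands[idx[which.max(scs[idx])]])
    }
    above <- which(scs >= high)
    if (!length(above)) break
    cur <- cands[above[which.min(scs[above])]]
  }
  stop("could not engineer a peptide in the requested score band")
}

#' Worked-example gene with a four-exon MXE cluster
#'
#' Builds a deterministic single-gene genome with three annotated exons
#' (1, 2b, 3) and three planted alternatives for the 18-amino-acid internal
#' exon 2b: exon 2a in the intron between exons 1 and 2b, and exons 2c and
#' 2d in the intron between 2b and 3.  The alternatives are engineered
#' against the display filters: 2a and 2d have a length difference of 12 and
#' 13 amino acids (within the default bound of 20 but removed when the bound
#' is lowered below 12) and score above 15\%; 2c has no length difference
#' but scores between 10\% and 15\%, so the default minimum score removes
#' exactly 2c while the relaxed store threshold of 10\% still finds it; and
#' because exon 2b is 18 amino acids long, a minimum original exon length
#' above 18 removes all three.
#'
#' @param params alignment settings used for the engineered scores (the
#'   thresholds themselves are fixed by the display/store presets).
#' @return list with \code{genome}, \code{annotation}, \code{proteins},
#'   and \code{expected}: a data.frame with one row per alternative
#'   (\code{name} 2a/2c/2d, genomic interval, engineered \code{score} and
#'   \code{lenDiffAa}, and the intron each lies in).
#' @export
fig2bFixture <- function(params = predictionParams()) {
  key <- paste("fig2b", params@matrix, params@gapOpen, params@gapExtend)
  if (is.null(.mxeCache[[key]]))
    .mxeCache[[key]] <- .withLocalSeed(20140210L, .fig2bImpl(params))
  .mxeCache[[key]]
}

.fig2bImpl <- function(params) {
  pep1 <- "MSTELKHQVNDARWFGYIPLCESTKVQHN"   # 29 aa, initiator M first
  pep2b <- "DKLQVERTWNAYFHGSIE"             # 18 aa: the original exon 2b
  pep3 <- "GHIKLANPQRSTVWYAEDGHIKLN"        # 24 aa before the stop
  stopifnot(nchar(pep2b) == 18)

  ins12 <- "ASGTNDKELQVR"                    # 12 aa insertion for 2a
  ins13 <- "WFYHPCMIKDNTS"                   # 13 aa insertion for 2d
  pep2a <- paste0(substr(pep2b, 1, 9), ins12, substr(pep2b, 10, 18))
  pep2d <- paste0(substr(pep2b, 1, 9), ins13, substr(pep2b, 10, 18))
  pep2c <- .degradeToScoreBand(pep2b, 10, 15, params)

  sc <- function(p) similarityScore(pep2b, p, params)
  stopifnot(sc(pep2a) >= 15, sc(pep2d) >= 15,
            sc(pep2c) >= 10, sc(pep2c) < 15)

  bt <- function(p) .backTranslate(p, deterministic = TRUE)
  exon1 <- bt(pep1)
  exon2b <- bt(pep2b)
  exon3 <- paste0(bt(pep3), "TAA")
  alt2a <- bt(pep2a)
  alt2c <- bt(pep2c)
  alt2d <- bt(pep2d)

  screen <- .screenParams()
  exonRow <- function(nt, idx, startLocal, isTerminal = FALSE) {
    data.frame(start = startLocal, end = startLocal + nchar(nt),
               ntLen = nchar(nt), startPhase = 0L,
               aaLen = nchar(nt) %/% 3L, peptide = exonPeptide(nt, 0L),
               isTerminal = isTerminal, stringsAsFactors = FALSE)
  }
  # the source exon (2b) must recover exactly the planted alternatives from
  # its side; the opposite flanking exon must recover nothing at all, so the
  # worked example yields precisely three candidates at the store stage
  buildIntron <- function(alts, leftNt, rightNt, rightTerminal, sourceSide) {
    for (try in seq_len(200)) {
      asm <- .assembleIntron(240L, alts)
      f1 <- .screenIntron(asm$seq, 0, exonRow(leftNt, 1L, -nchar(leftNt)),
                          screen)
      f2 <- .screenIntron(asm$seq, 0,
                          exonRow(rightNt, 2L, nchar(asm$seq),
                                  isTerminal = rightTerminal), screen)
      plantedKeys <- paste(asm$plantLocal[, 1], asm$plantLocal[, 2])
      src <- if (sourceSide == "left") f1 else f2
      oth <- if (sourceSide == "left") f2 else f1
      if (setequal(paste(src$start, src$end), plantedKeys) &&
          nrow(oth) == 0L)
        return(asm)
    }
    stop("could not assemble a decoy-free worked-example intron")
  }
  intron1 <- buildIntron(alt2a, exon1, exon2b, FALSE, sourceSide = "right")
  intron2 <- buildIntron(c(alt2c, alt2d), exon2b, exon3, TRUE,
                         sourceSide = "left")

  pad <- 200L
  parts <- c(.randNt(pad), exon1, intron1$seq, exon2b, intron2$seq, exon3,
             .randNt(pad))
  starts <- cumsum(c(0L, nchar(parts)))
  genome <- DNAStringSet(c(chrF = paste(parts, collapse = "")))

  exonStart <- c(starts[2], starts[4], starts[6])
  exonNt <- c(nchar(exon1), nchar(exon2b), nchar(exon3))
  ann <- data.frame(geneId = "g2b", proteinId = "g2b.1", targetId = "chrF",
                    start = exonStart, end = exonStart + exonNt,
                    strand = "+", phase = 0L, stringsAsFactors = FALSE)

  i1 <- starts[3]   # genomic start of intron 1
  i2 <- starts[5]
  expected <- data.frame(
    name = c("2a", "2c", "2d"),
    start = c(i1 + intron1$plantLocal[1, 1],
              i2 + intron2$plantLocal[1, 1],
              i2 + intron2$plantLocal[2, 1]),
    end = c(i1 + intron1$plantLocal[1, 2],
            i2 + intron2$plantLocal[1, 2],
            i2 + intron2$plantLocal[2, 2]),
    location = c("upstream_intron", "downstream_intron", "downstream_intron"),
    score = c(sc(pep2a), sc(pep2c), sc(pep2d)),
    lenDiffAa = c(12L, 0L, 13L),
    stringsAsFactors = FALSE)

  proteins <- AAStringSet(c(g2b.1 = paste0(pep1, pep2b, pep3)))
  list(genome = genome, annotation = ann, proteins = proteins,
       expected = expected)
}
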