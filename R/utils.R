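# Internal helpers: coordinates, sequence access, RNG scoping.
#
# All internal coordinates are 0-based half-open intervals on the forward
# genomic strand; strand is carried separately and conversion to/from the
# 1-based inclusive GFF3 convention happens only at format boundaries.

# genomic [start, end) on the forward strand -> character sequence
.subSeq <- function(genome, targetId, start, end) {
  if (!targetId %in% names(genome))
    stop("unknown target sequence: ", targetId)
  len <- width(genome)[match(targetId, names(genome))]
  if (start < 0L || end > len || start > end)
    stop("interval [", start, ",", end, ") outside target ", targetId,
         " (length ", len, ")")
  as.character(subseq(genome[[targetId]], start + 1L, end))
}

.revComp <- function(x) {
  vapply(x, function(s) {
    if (!nzchar(s)) return("")
    as.character(reverseComplement(DNAString(s)))
  }, character(1), USE.NAMES = FALSE)
}

# sequence of [start, end) read on the coding strand
.codingSeq <- function(genome, targetId, start, end, strand) {
  s <- .subSeq(genome, targetId, start, end)
  if (strand == "-") .revComp(s) else s
}

# map a local (1-based, closed, coding-strand) interval back to a genomic
# 0-based half-open interval, given the genomic region [gStart, gEnd) it was
# extracted from
.localToGenomic <- function(a, b, gStart, gEnd, strand) {
  if (strand == "-") c(gEnd - b, gEnd - a + 1L) else c(gStart + a - 1L, gStart + b)
}

# translate complete codons of a coding-strand nucleotide string
.translateCodons <- function(nt) {
  n <- (nchar(nt) %/% 3L) * 3L
  if (n < 3L) return("")
  as.character(translate(DNAString(substr(nt, 1L, n)),
                         genetic.code = GENETIC_CODE, no.init.codon = TRUE))
}

# vectorised variant for many candidate sequences (already phase-trimmed)
.translateCodonsMany <- function(nts) {
  if (!length(nts)) return(character(0))
  n <- (nchar(nts) %/% 3L) * 3L
  out <- character(length(nts))
  ok <- n >= 3L
  if (any(ok)) {
    trimmed <- substr(nts[ok], 1L, n[ok])
    out[ok] <- as.character(translate(DNAStringSet(trimmed),
                                      genetic.code = GENETIC_CODE,
                                      no.init.codon = TRUE))
  }
  out
}

# evaluate expr under a fixed RNG seed without disturbing the caller's stream
.withLocalSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(expr)
}

.overlaps <- function(s1, e1, s2, e2) s1 < e2 & s2 < e1

# substitution matrix lookup with caching; matrices ship with Biostrings
.subMatrix <- function(name) {
  key <- paste0("mat_", name)
  if (!is.null(.mxeCache[[key]])) return(.mxeCache[[key]])
  e <- new.env()
  ok <- tryCatch({
    data(list = name, package = "Biostrings", envir = e)
    TRUE
  }, warning = function(w) FALSE, error = function(e) FALSE)
  if (!ok || !exists(name, envir = e))
    stop("unknown substitution matrix: ", name)
  .mxeCache[[key]] <- get(name, envir = e)
  .mxeCache[[key]]
}

# zero-row candidate table with the full column contract
.emptyCandidates <- function() {
  data.frame(
    candidateId = character(0), geneId = character(0),
    proteinId = character(0), sourceExonIndex = integer(0),
    sourceExonStart = numeric(0), sourceExonEnd = numeric(0),
    sourceNtLen = integer(0), sourceAaLen = integer(0),
    targetId = character(0), start = numeric(0), end = numeric(0),
    strand = character(0), location = character(0),
    acceptor = character(0), donor = character(0),
    ntLen = integer(0), lenDiffAa = integer(0), score = numeric(0),
    peptide = character(0), flankDistNt = numeric(0),
    flagExactMatch = logical(0), flagIsoformOverlap = logical(0),
    flagNeighbourOverlap = logical(0),
    stringsAsFactors = FALSE)
}

.locationLevels <- c("upstream_flank", "upstream_intron", "other_intron",
                     "downstream_intron", "downstream_flank")

# deterministic candidate ordering: source isoform, source exon, location
# class (5' to 3'), genomic start
.orderCandidates <- function(df) {
  if (!nrow(df)) return(df)
  loc <- match(df$location, .locationLevels)
  df[order(df$geneId, df$proteinId, df$sourceExonIndex, loc, df$start,
           df$end), , drop = FALSE]
}

.assignCandidateIds <- function(df) {
  if (!nrow(df)) return(df)
  df$candidateId <- paste(df$geneId, df$proteinId,
                          paste0("e", df$sourceExonIndex), df$location,
                          paste0(df$start, "-", df$end), sep = "|")
  df
}
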