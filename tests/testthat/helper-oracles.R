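# Independent oracles, deliberately written without reference to the package
# internals: a Gotoh dynamic-programming global aligner, a codon-table
# translator, and a literal O(n^2) brute-force candidate enumerator.

.oracleBlosum <- local({
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  e$BLOSUM62
})

# affine-gap global alignment score; a gap of length L costs open + L * ext,
# end gaps penalized (Gotoh, three matrices)
oracleAlignScore <- function(a, b, mat = .oracleBlosum, open = 11, ext = 1) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  n <- length(A)
  m <- length(B)
  NEG <- -1e15
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)  # gap in b (consumes a)
  Y <- matrix(NEG, n + 1, m + 1)  # gap in a (consumes b)
  M[1, 1] <- 0
  if (n >= 1) for (i in 2:(n + 1)) X[i, 1] <- -(open + (i - 1) * ext)
  if (m >= 1) for (j in 2:(m + 1)) Y[1, j] <- -(open + (j - 1) * ext)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- mat[A[i - 1], B[j - 1]]
      M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
      X[i, j] <- max(M[i - 1, j] - open - ext, X[i - 1, j] - ext)
      Y[i, j] <- max(M[i, j - 1] - open - ext, Y[i, j - 1] - ext)
    }
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

oracleSimilarity <- function(orig, cand, open = 11, ext = 1) {
  100 * oracleAlignScore(orig, cand, open = open, ext = ext) /
    oracleAlignScore(orig, orig, open = open, ext = ext)
}

# standard nuclear genetic code, written out independently
.oracleCodons <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L", CTT = "L", CTC = "L",
  CTA = "L", CTG = "L", ATT = "I", ATC = "I", ATA = "I", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V", TCT = "S", TCC = "S",
  TCA = "S", TCG = "S", CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T", GCT = "A", GCC = "A",
  GCA = "A", GCG = "A", TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q", AAT = "N", AAC = "N",
  AAA = "K", AAG = "K", GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "*", TGG = "W", CGT = "R", CGC = "R",
  CGA = "R", CGG = "R", AGT = "S", AGC = "S", AGA = "R", AGG = "R",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

oracleTranslate <- function(nt, phase = 0) {
  nt <- substr(nt, phase + 1, nchar(nt))
  k <- nchar(nt) %/% 3
  if (k == 0) return("")
  codons <- substring(nt, 3 * seq_len(k) - 2, 3 * seq_len(k))
  paste(.oracleCodons[codons], collapse = "")
}

# literal brute force over all AG/GT(GC)-bounded position pairs with the
# same predicates as the candidate search (no overlap resolution)
oracleEnumerate <- function(regionSeq, srcNtLen, srcPhase, srcPep,
                            srcIsTerminal, minScore, maxLenDiff, margin,
                            open = 11, ext = 1) {
  n <- nchar(regionSeq)
  out <- data.frame(start = integer(0), end = integer(0), score = numeric(0))
  selfScore <- oracleAlignScore(srcPep, srcPep, open = open, ext = ext)
  for (i in seq_len(n)) {          # local 1-based candidate start
    if (i < 3 || substr(regionSeq, i - 2, i - 1) != "AG") next
    if (i - 1 < margin) next
    for (j in i:n) {               # local 1-based candidate end
      if (j + 2 > n) break
      if (!substr(regionSeq, j + 1, j + 2) %in% c("GT", "GC")) next
      if (n - j < margin) next
      L <- j - i + 1
      if ((L - srcNtLen) %% 3 != 0) next
      if (abs(L - srcNtLen) / 3 > maxLenDiff) next
      if (L < srcPhase + 3) next
      cand <- substr(regionSeq, i, j)
      if (grepl("N", cand)) next
      pep <- oracleTranslate(cand, srcPhase)
      if (!nzchar(pep)) next
      internal <- substr(pep, 1, nchar(pep) - 1)
      if (grepl("*", internal, fixed = TRUE)) next
      lastAa <- substr(pep, nchar(pep), nchar(pep))
      if (!srcIsTerminal && lastAa == "*") next
      sc <- 100 * oracleAlignScore(srcPep, pep, open = open, ext = ext) /
        selfScore
      if (sc < minScore) next
      out <- rbind(out, data.frame(start = i - 1, end = j, score = sc))
    }
  }
  out
}

# random intron with a planted copy of a source exon (for enumeration tests)
randomIntronWithPlant <- function(len, plantNt = NULL, margin = 30) {
  inner <- paste(sample(c("A", "C", "G", "T"), len - 4, replace = TRUE),
                 collapse = "")
  if (!is.null(plantNt)) {
    at <- margin
    inner <- paste0(substr(inner, 1, at), "AG", plantNt, "GT",
                    substr(inner, at + 1, nchar(inner)))
  }
  paste0("GT", inner, "AG")
}
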