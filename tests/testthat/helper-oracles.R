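## Independent oracles used by the tests. These deliberately re-derive the
## quantities by the most direct route available (exhaustive enumeration,
## elemental composition) and share no code with the package internals.

AA_LETTERS <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
                "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

## --- digestion oracle: enumerate all substrings, classify each terminus
## directly from the cleavage rule (after K/R unless next residue is P;
## protein termini count as tryptic) -----------------------------------

oracleTermini <- function(letters, s, e) {
  n <- length(letters)
  ntryp <- s == 1 ||
    (letters[s - 1] %in% c("K", "R") && letters[s] != "P")
  ctryp <- e == n ||
    (letters[e] %in% c("K", "R") && letters[e + 1] != "P")
  c(n = ntryp, c = ctryp)
}

oracleMissed <- function(letters, s, e) {
  if (e == s) return(0L)
  cnt <- 0L
  for (i in s:(e - 1L))
    if (letters[i] %in% c("K", "R") && letters[i + 1L] != "P")
      cnt <- cnt + 1L
  cnt
}

## all fully tryptic peptides with <= maxMissed internal sites
oracleDigest <- function(sequence, maxMissed) {
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  out <- list()
  for (s in 1:n) for (e in s:n) {
    tt <- oracleTermini(letters, s, e)
    if (tt["n"] && tt["c"] && oracleMissed(letters, s, e) <= maxMissed)
      out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(start = m[, 1], end = m[, 2])
  d[order(d$start, d$end), ]
}

## all peptides with exactly one tryptic terminus and length in bounds
oracleSemi <- function(sequence, minLen, maxLen) {
  letters <- strsplit(sequence, "")[[1]]
  n <- length(letters)
  out <- list()
  for (s in 1:n) for (e in s:n) {
    len <- e - s + 1L
    if (len < minLen || len > maxLen) next
    tt <- oracleTermini(letters, s, e)
    if (sum(tt) == 1L) out[[length(out) + 1L]] <- c(s, e)
  }
  if (!length(out)) return(data.frame(start = integer(), end = integer()))
  m <- do.call(rbind, out)
  d <- data.frame(start = m[, 1], end = m[, 2])
  d[order(d$start, d$end), ]
}

## --- elemental-composition mass oracle --------------------------------
## residue formulas (CHNOS counts) and monoisotopic atomic masses; fully
## independent of the package's 5-decimal residue table

RESIDUE_FORMULA <- list(
  G = c(2, 3, 1, 1, 0),  A = c(3, 5, 1, 1, 0),  S = c(3, 5, 1, 2, 0),
  P = c(5, 7, 1, 1, 0),  V = c(5, 9, 1, 1, 0),  T = c(4, 7, 1, 2, 0),
  C = c(3, 5, 1, 1, 1),  L = c(6, 11, 1, 1, 0), I = c(6, 11, 1, 1, 0),
  N = c(4, 6, 2, 2, 0),  D = c(4, 5, 1, 3, 0),  Q = c(5, 8, 2, 2, 0),
  K = c(6, 12, 2, 1, 0), E = c(5, 7, 1, 3, 0),  M = c(5, 9, 1, 1, 1),
  H = c(6, 7, 3, 1, 0),  F = c(9, 9, 1, 1, 0),  R = c(6, 12, 4, 1, 0),
  Y = c(9, 9, 1, 2, 0),  W = c(11, 10, 2, 1, 0))

ATOM_MONO <- c(C = 12, H = 1.0078250319, N = 14.0030740052,
               O = 15.9949146221, S = 31.97207069)

oracleResidueMass <- function(letter) {
  f <- RESIDUE_FORMULA[[letter]]
  sum(f * ATOM_MONO[c("C", "H", "N", "O", "S")])
}

oraclePeptideMass <- function(sequence) {
  letters <- strsplit(sequence, "")[[1]]
  sum(vapply(letters, oracleResidueMass, 0)) +
    2 * ATOM_MONO["H"] + ATOM_MONO["O"]   # + water
}

randomPeptide <- function(minLen = 2L, maxLen = 20L) {
  paste(sample(AA_LETTERS, sample(minLen:maxLen, 1L), replace = TRUE),
        collapse = "")
}
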