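## In-silico proteolysis: fully tryptic digestion with missed cleavages,
## semi-tryptic enumeration (one subtilisin cut + trypsin), and locating
## peptides on a protein. Trypsin cleaves C-terminal to K/R, suppressed when
## the next residue is P (the Mascot default rule); protein N/C termini
## count as tryptic termini.

## logical vector over positions 1..n-1: is there a cleavage site after i?
cleavageAfter <- function(letters) {
  n <- length(letters)
  if (n < 2L) return(logical(0))
  letters[-n] %in% c("K", "R") & letters[-1L] != "P"
}

## tryptic status of an N-terminus starting at s / C-terminus ending at e
ntermTryptic <- function(letters, cleav) {
  n <- length(letters)
  c(TRUE, if (n > 1L) cleav)   # position s tryptic iff s == 1 or site after s-1
}
ctermTryptic <- function(letters, cleav) {
  n <- length(letters)
  c(if (n > 1L) cleav, TRUE)   # position e tryptic iff e == n or site after e
}

peptideFrame <- function(proteinId, seqString, start, end, nMissed, status) {
  if (!length(start))
    return(data.frame(protein_id = character(), start = integer(),
                      end = integer(), sequence = character(),
                      n_missed = integer(), terminal_status = character(),
                      stringsAsFactors = FALSE))
  data.frame(protein_id = proteinId, start = as.integer(start),
             end = as.integer(end),
             sequence = substring(seqString, start, end),
             n_missed = as.integer(nMissed), terminal_status = status,
             stringsAsFactors = FALSE)
}

#' Fully tryptic in-silico digestion
#'
#' Enumerates every fully tryptic peptide with up to `maxMissed` missed
#' cleavages. Cleavage occurs after K or R except when the following
#' residue is P; the protein N- and C-termini count as tryptic, so
#' protein-terminal peptides are fully tryptic. Peptides with 0 missed
#' cleavages tile the protein exactly.
#'
#' @param protein a [ProteinRecord-class] (or a plain sequence string).
#' @param maxMissed maximum number of internal missed K/R cleavage sites
#'   (default 0).
#' @return `data.frame` with columns `protein_id`, `start`, `end`
#'   (1-based inclusive), `sequence`, `n_missed`, `terminal_status`
#'   (always `"fully_tryptic"`), ordered by (start, end).
#' @examples
#' digestTryptic(ProteinRecord("p", "AKRPC"), maxMissed = 1)
#' @export
digestTryptic <- function(protein, maxMissed = 0L) {
  if (maxMissed < 0) stop("maxMissed must be >= 0", call. = FALSE)
  if (is.character(protein)) protein <- ProteinRecord("protein", protein)
  seqString <- proteinSequence(protein)
  letters <- strsplit(seqString, "", fixed = TRUE)[[1]]
  cleav <- cleavageAfter(letters)
  n <- length(letters)
  sites <- which(cleav)                     # cleavage after these positions
  starts <- c(1L, sites + 1L)
  ends <- c(sites, n)
  m <- length(starts)                       # number of 0-missed fragments
  rows <- list()
  for (i in seq_len(m)) {
    for (k in 0:min(maxMissed, m - i)) {
      rows[[length(rows) + 1L]] <-
        c(start = starts[i], end = ends[i + k], n_missed = k)
    }
  }
  tab <- as.data.frame(do.call(rbind, rows))
  tab <- tab[order(tab$start, tab$end), , drop = FALSE]
  peptideFrame(proteinId(protein), seqString, tab$start, tab$end,
               tab$n_missed, "fully_tryptic")
}

#' Enumerate semi-tryptic peptides
#'
#' All peptides with length in `[minLen, maxLen]` carrying exactly one
#' tryptic terminus — the products of one non-specific (subtilisin) cut
#' combined with trypsin. Fully tryptic peptides are excluded; the result
#' is disjoint from [digestTryptic()] output by construction.
#'
#' @inheritParams digestTryptic
#' @param minLen,maxLen inclusive peptide length bounds
#'   (`1 <= minLen <= maxLen`).
#' @return `data.frame` as in [digestTryptic()] with `terminal_status
#'   = "semi_tryptic"`; empty when `minLen` exceeds the protein length.
#' @export
enumerateSemitryptic <- function(protein, minLen, maxLen) {
  if (minLen < 1 || minLen > maxLen)
    stop("need 1 <= minLen <= maxLen", call. = FALSE)
  if (is.character(protein)) protein <- ProteinRecord("protein", protein)
  seqString <- proteinSequence(protein)
  letters <- strsplit(seqString, "", fixed = TRUE)[[1]]
  n <- length(letters)
  cleav <- cleavageAfter(letters)
  ntryp <- ntermTryptic(letters, cleav)
  ctryp <- ctermTryptic(letters, cleav)
  if (minLen > n)
    return(peptideFrame(proteinId(protein), seqString, integer(),
                        integer(), integer(), character()))
  starts <- integer(); ends <- integer()
  for (len in seq(minLen, min(maxLen, n))) {
    s <- seq_len(n - len + 1L)
    e <- s + len - 1L
    semi <- xor(ntryp[s], ctryp[e])
    starts <- c(starts, s[semi]); ends <- c(ends, e[semi])
  }
  if (!length(starts))
    return(peptideFrame(proteinId(protein), seqString, integer(), integer(),
                        integer(), character()))
  ord <- order(starts, ends)
  starts <- starts[ord]; ends <- ends[ord]
  ## internal missed sites of [s, e] are cleavage sites after positions s..e-1
  nm <- vapply(seq_along(starts), function(i) {
    if (ends[i] == starts[i]) 0L
    else sum(cleav[seq(starts[i], ends[i] - 1L)])
  }, integer(1))
  peptideFrame(proteinId(protein), seqString, starts, ends, nm,
               "semi_tryptic")
}

#' Locate a peptide sequence on a protein
#'
#' All (possibly overlapping) occurrences of `peptideSequence` in the
#' protein, 1-based inclusive; empty when absent.
#'
#' @inheritParams digestTryptic
#' @param peptideSequence non-empty query sequence.
#' @return `data.frame` with columns `start`, `end`.
#' @export
mapPeptide <- function(protein, peptideSequence) {
  if (!nzchar(peptideSequence))
    stop("peptideSequence must be non-empty", call. = FALSE)
  if (is.character(protein)) protein <- ProteinRecord("protein", protein)
  stopIfInvalidSequence(peptideSequence)
  hits <- Biostrings::matchPattern(
    toupper(peptideSequence),
    Biostrings::AAString(proteinSequence(protein)))
  data.frame(start = BiocGenerics::start(hits),
             end = BiocGenerics::end(hits))
}
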