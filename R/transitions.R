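## MRM transition candidate design: the in-silico stand-in for a
## PeptideAtlas/SRMAtlas lookup. Quantifiable peptides are fully tryptic
## with 0 missed cleavages and length within bounds; per peptide the top-K
## singly charged y-ions above a low-mass cutoff are kept, ranked by
## fragment index descending (longer y-ions are the usual first choice).

#' Design MRM transition candidates for a protein
#'
#' Deterministic in-silico transition selection: fully tryptic peptides
#' with 0 missed cleavages and length within `[minLen, maxLen]`, optionally
#' excluding peptides containing given residues; for each peptide and each
#' precursor charge state, the top `nFragments` singly charged y-ions with
#' m/z above `mzCutoff`, ranked by fragment index descending. The output is
#' sorted by peptide start position.
#'
#' @inheritParams digestTryptic
#' @param minLen,maxLen peptide length bounds (defaults 6 and 25).
#' @param charges precursor charge states to emit (default `c(2, 3)`).
#' @param nFragments number of y-ions per peptide/charge (default 3;
#'   clamped to the available ions).
#' @param mzCutoff lowest fragment m/z retained (default 300).
#' @param excludeResidues residues whose presence disqualifies a peptide
#'   (default none).
#' @param mods modification names applied to all masses, as in
#'   [peptideMass()].
#' @return `data.frame` with one row per transition: `protein_id`,
#'   `peptide`, `start`, `end`, `precursor_mz`, `precursor_z`,
#'   `fragment_series`, `fragment_index`, `fragment_z`, `fragment_mz`.
#' @export
selectTransitions <- function(protein, minLen = 6L, maxLen = 25L,
                              charges = c(2L, 3L), nFragments = 3L,
                              mzCutoff = 300, excludeResidues = character(),
                              mods = "carbamidomethyl") {
  if (is.character(protein)) protein <- ProteinRecord("protein", protein)
  if (!all(charges %in% c(2L, 3L)))
    stop("precursor charges must be drawn from {2, 3}", call. = FALSE)
  empty <- data.frame(
    protein_id = character(), peptide = character(), start = integer(),
    end = integer(), precursor_mz = numeric(), precursor_z = integer(),
    fragment_series = character(), fragment_index = integer(),
    fragment_z = integer(), fragment_mz = numeric(),
    stringsAsFactors = FALSE)
  if (proteinLength(protein) < minLen) {
    warning(sprintf("protein '%s' (%d residues) is shorter than minLen = %d; no candidates",
                    proteinId(protein), proteinLength(protein), minLen))
    return(empty)
  }
  peps <- digestTryptic(protein, maxMissed = 0L)
  len <- peps$end - peps$start + 1L
  peps <- peps[len >= minLen & len <= maxLen, , drop = FALSE]
  if (length(excludeResidues)) {
    bad <- vapply(peps$sequence, function(s)
      any(strsplit(s, "", fixed = TRUE)[[1]] %in% excludeResidues),
      logical(1))
    peps <- peps[!bad, , drop = FALSE]
  }
  if (!nrow(peps)) return(empty)
  rows <- lapply(seq_len(nrow(peps)), function(i) {
    pep <- peps[i, ]
    mass <- peptideMass(pep$sequence, mods = mods)
    frags <- fragmentIons(pep$sequence, maxCharge = 1L, mods = mods)
    y <- frags[frags$series == "y" & frags$mz >= mzCutoff, , drop = FALSE]
    y <- y[order(y$index, decreasing = TRUE), , drop = FALSE]
    y <- head(y, nFragments)
    if (!nrow(y)) return(NULL)
    do.call(rbind, lapply(sort(charges), function(z) {
      data.frame(
        protein_id = pep$protein_id, peptide = pep$sequence,
        start = pep$start, end = pep$end,
        precursor_mz = precursorMz(mass, z), precursor_z = as.integer(z),
        fragment_series = y$series, fragment_index = y$index,
        fragment_z = y$charge, fragment_mz = y$mz,
        stringsAsFactors = FALSE)
    }))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(out$start, out$end, out$precursor_z,
                   -out$fragment_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write a transition candidate table as TSV
#'
#' @param transitions output of [selectTransitions()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
writeTransitionTable <- function(transitions, path) {
  write.table(transitions, path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
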