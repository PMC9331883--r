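## Residue mass tables, peptide/fragment mass arithmetic, m/z conversion.
## Monoisotopic and average residue masses to 5 decimals; proton and water
## constants are the usual proteomics values.

PROTON_MASS <- 1.007276
WATER_MONO <- 18.010565
WATER_AVG <- 18.01528

RESIDUE_MONO <- c(
  G = 57.02146, A = 71.03711, S = 87.03203, P = 97.05276, V = 99.06841,
  T = 101.04768, C = 103.00919, L = 113.08406, I = 113.08406,
  N = 114.04293, D = 115.02694, Q = 128.05858, K = 128.09496,
  E = 129.04259, M = 131.04049, H = 137.05891, F = 147.06841,
  R = 156.10111, Y = 163.06333, W = 186.07931)

RESIDUE_AVG <- c(
  G = 57.05192, A = 71.07880, S = 87.07820, P = 97.11668, V = 99.13256,
  T = 101.10508, C = 103.13880, L = 113.15944, I = 113.15944,
  N = 114.10384, D = 115.08860, Q = 128.13072, K = 128.17408,
  E = 129.11548, M = 131.19256, H = 137.14108, F = 147.17656,
  R = 156.18748, Y = 163.17596, W = 186.21320)

## mass deltas in Da: c(monoisotopic, average); target residue letter
SUPPORTED_MODS <- list(
  carbamidomethyl = list(residue = "C", mono = 57.02146, avg = 57.05130),
  oxidation       = list(residue = "M", mono = 15.99491, avg = 15.99940),
  phospho         = list(residue = c("S", "T"), mono = 79.96633,
                         avg = 79.97990))

checkModNames <- function(mods) {
  unknown <- setdiff(mods, names(SUPPORTED_MODS))
  if (length(unknown))
    stop(sprintf("unknown modification(s) %s; supported modifications: %s",
                 paste(sQuote(unknown), collapse = ", "),
                 paste(names(SUPPORTED_MODS), collapse = ", ")),
         call. = FALSE)
  invisible(TRUE)
}

## per-residue mass vector for a peptide, with named modifications applied
## to every matching residue
residueMasses <- function(sequence, mods, kind) {
  stopIfInvalidSequence(sequence)
  checkModNames(mods)
  letters <- strsplit(toupper(sequence), "", fixed = TRUE)[[1]]
  table <- if (kind == "monoisotopic") RESIDUE_MONO else RESIDUE_AVG
  masses <- unname(table[letters])
  for (m in mods) {
    spec <- SUPPORTED_MODS[[m]]
    hit <- letters %in% spec$residue
    masses[hit] <- masses[hit] +
      if (kind == "monoisotopic") spec$mono else spec$avg
  }
  masses
}

#' Peptide neutral mass
#'
#' Sum of residue masses plus one water. Named modifications are applied to
#' every matching residue: `"carbamidomethyl"` (+57.02146 Da monoisotopic on
#' C, the usual fixed alkylation), `"oxidation"` (+15.99491 Da on M),
#' `"phospho"` (+79.96633 Da on S/T).
#'
#' @param sequence peptide sequence over the 20 standard residue letters.
#' @param mods character vector of modification names to apply
#'   (default: fixed carbamidomethylation of cysteines).
#' @param kind `"monoisotopic"` (default) or `"average"`.
#' @return neutral mass in Da.
#' @examples
#' peptideMass("PEPTIDE", mods = character()) # 799.35997
#' @export
peptideMass <- function(sequence, mods = "carbamidomethyl",
                        kind = c("monoisotopic", "average")) {
  kind <- match.arg(kind)
  water <- if (kind == "monoisotopic") WATER_MONO else WATER_AVG
  sum(residueMasses(sequence, mods, kind)) + water
}

#' Precursor m/z from neutral mass and charge
#'
#' @param neutralMass neutral mass in Da.
#' @param charge positive integer charge state.
#' @return m/z in Da per unit charge: `(neutralMass + charge * 1.007276) /
#'   charge`.
#' @export
precursorMz <- function(neutralMass, charge) {
  if (any(charge <= 0) || any(charge != as.integer(charge)))
    stop("charge must be a positive integer", call. = FALSE)
  (neutralMass + charge * PROTON_MASS) / charge
}

#' b- and y-series fragment ions of a peptide
#'
#' Neutral b_i is the sum of the first i residue masses; neutral y_j is the
#' sum of the last j residue masses plus water. Modifications travel with
#' the fragment containing the modified residue. For every index i and
#' charge 1, `mz(b_i) + mz(y_(n-i))` equals the neutral peptide mass plus
#' two protons (the b/y complementarity identity).
#'
#' @param sequence peptide sequence (length >= 2).
#' @param maxCharge highest fragment charge state to emit (default 1).
#' @param mods modification names, as in [peptideMass()].
#' @return `data.frame` with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`.
#' @export
fragmentIons <- function(sequence, maxCharge = 1L, mods = "carbamidomethyl") {
  n <- nchar(sequence)
  if (n < 2L) stop("peptide must have at least 2 residues", call. = FALSE)
  masses <- residueMasses(sequence, mods, "monoisotopic")
  bNeutral <- cumsum(masses)[-n]
  yNeutral <- cumsum(rev(masses))[-n] + WATER_MONO
  out <- do.call(rbind, lapply(seq_len(maxCharge), function(z) {
    data.frame(
      series = rep(c("b", "y"), each = n - 1L),
      index = rep(seq_len(n - 1L), 2L),
      charge = z,
      mz = c(precursorMz(bNeutral, z), precursorMz(yNeutral, z)),
      stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
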