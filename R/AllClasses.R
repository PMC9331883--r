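#' @import methods
#' @importFrom stats median quantile rlnorm rnorm runif sd setNames coef
#'   cor lm nls predict t.test approx resid
#' @importFrom utils head read.delim write.table read.csv
NULL

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

ANNOTATION_KINDS <- c("domain", "helix", "loop", "residue")

#' ProteinRecord: a protein sequence with a structural annotation track
#'
#' The central container of the package: an identifier, an amino-acid
#' sequence over the 20 standard residue letters, and an annotation track of
#' named residue intervals (domains, helices, loops, single key residues).
#' All coordinates are 1-based and inclusive throughout the package,
#' matching the field's "peptide 71--78" notation.
#'
#' @slot id single protein identifier.
#' @slot sequence amino-acid sequence (uppercase, 20-letter alphabet;
#'   ambiguity codes B, J, O, U, X, Z are rejected).
#' @slot annotations `data.frame` with columns `name`, `start`, `end`,
#'   `kind` (one of `domain`, `helix`, `loop`, `residue`); intervals are
#'   1-based inclusive and must lie within the sequence.
#'
#' @seealso [ProteinRecord()] for construction, [digestTryptic()],
#'   [mapRegions()].
#' @exportClass ProteinRecord
setClass("ProteinRecord",
  representation(id = "character", sequence = "character",
                 annotations = "data.frame"))

emptyAnnotations <- function() {
  data.frame(name = character(), start = integer(), end = integer(),
             kind = character(), stringsAsFactors = FALSE)
}

setValidity("ProteinRecord", function(object) {
  msg <- character()
  if (length(object@id) != 1L || is.na(object@id) || !nzchar(object@id))
    msg <- c(msg, "'id' must be a single non-empty string")
  if (length(object@sequence) != 1L || is.na(object@sequence) ||
      !nzchar(object@sequence))
    msg <- c(msg, "'sequence' must be a single non-empty string")
  else {
    bad <- badResiduePositions(object@sequence)
    if (length(bad))
      msg <- c(msg, sprintf(
        "invalid residue letter '%s' at position %d (B, J, O, U, X, Z and non-amino-acid characters are not allowed)",
        substring(object@sequence, bad[1], bad[1]), bad[1]))
  }
  ann <- object@annotations
  need <- c("name", "start", "end", "kind")
  if (!all(need %in% names(ann)))
    msg <- c(msg, "annotations must have columns name, start, end, kind")
  else if (nrow(ann)) {
    n <- nchar(object@sequence)
    if (any(!ann$kind %in% ANNOTATION_KINDS))
      msg <- c(msg, sprintf("annotation kind must be one of %s",
                            paste(ANNOTATION_KINDS, collapse = ", ")))
    if (any(ann$start < 1L | ann$end < ann$start | ann$end > n))
      msg <- c(msg, "annotation intervals must satisfy 1 <= start <= end <= protein length")
  }
  if (length(msg)) msg else TRUE
})

badResiduePositions <- function(sequence) {
  letters <- strsplit(sequence, "", fixed = TRUE)[[1]]
  which(!letters %in% AA20)
}

#' Construct a ProteinRecord
#'
#' @param id protein identifier (a single string).
#' @param sequence amino-acid sequence over the 20 standard letters;
#'   lowercase input is uppercased.
#' @param annotations optional `data.frame` with columns `name`, `start`,
#'   `end`, `kind` (1-based inclusive intervals; `kind` one of `domain`,
#'   `helix`, `loop`, `residue`). Single residues are intervals with
#'   `start == end`.
#' @return a validated [ProteinRecord-class] object.
#' @examples
#' p <- ProteinRecord("toy", "MAGKPEPTIDEK")
#' proteinSequence(p)
#' @export
ProteinRecord <- function(id, sequence, annotations = emptyAnnotations()) {
  sequence <- toupper(as.character(sequence))
  ann <- as.data.frame(annotations, stringsAsFactors = FALSE)
  if (nrow(ann)) {
    ann$start <- as.integer(ann$start)
    ann$end <- as.integer(ann$end)
    ann$name <- as.character(ann$name)
    ann$kind <- as.character(ann$kind)
  } else ann <- emptyAnnotations()
  new("ProteinRecord", id = as.character(id), sequence = sequence,
      annotations = ann)
}

#' @describeIn ProteinRecord protein identifier accessor.
#' @param x a `ProteinRecord`.
#' @export
proteinId <- function(x) x@id

#' @describeIn ProteinRecord sequence accessor (single string).
#' @export
proteinSequence <- function(x) x@sequence

#' @describeIn ProteinRecord annotation-track accessor (`data.frame`).
#' @export
annotations <- function(x) x@annotations

#' @describeIn ProteinRecord number of residues.
#' @export
proteinLength <- function(x) nchar(x@sequence)

setMethod("show", "ProteinRecord", function(object) {
  n <- nchar(object@sequence)
  cat(sprintf("ProteinRecord '%s': %d residues\n", object@id, n))
  preview <- if (n > 60L) paste0(substring(object@sequence, 1L, 57L), "...")
             else object@sequence
  cat("  ", preview, "\n", sep = "")
  if (nrow(object@annotations))
    cat(sprintf("  %d annotation(s): %s\n", nrow(object@annotations),
                paste(head(object@annotations$name, 5L), collapse = ", ")))
})

setMethod("length", "ProteinRecord", function(x) nchar(x@sequence))

stopIfInvalidSequence <- function(sequence) {
  bad <- badResiduePositions(toupper(sequence))
  if (length(bad))
    stop(sprintf(
      "invalid residue letter '%s' at position %d (allowed alphabet: %s)",
      substring(toupper(sequence), bad[1], bad[1]), bad[1],
      paste(AA20, collapse = "")), call. = FALSE)
  invisible(TRUE)
}
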