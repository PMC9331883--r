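## Readers and writers for the pipeline's plain-text interfaces. All
## residue coordinates in every file are 1-based inclusive. Tables are
## validated against their schema on read; reports go out as JSON plus a
## human-readable markdown table.

requireColumns <- function(tab, need, path) {
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop(sprintf("file '%s': missing column(s) %s", path,
                 paste(miss, collapse = ", ")), call. = FALSE)
  invisible(TRUE)
}

#' Read proteins from a FASTA file
#'
#' Standard (wrapped or unwrapped) FASTA; the record id is the first
#' whitespace-delimited token of the description line. Duplicate ids are
#' an error.
#'
#' @param path FASTA file.
#' @param annotations optional annotation track `data.frame` (applied to
#'   every record) or the result of [readAnnotationTrack()].
#' @return list of [ProteinRecord-class] objects, named by id.
#' @export
readProteinFasta <- function(path, annotations = NULL) {
  seqs <- Biostrings::readAAStringSet(path)
  ids <- vapply(strsplit(names(seqs), "\\s+"), `[`, "", 1L)
  if (anyDuplicated(ids))
    stop(sprintf("file '%s': duplicate protein id(s): %s", path,
                 paste(unique(ids[duplicated(ids)]), collapse = ", ")),
         call. = FALSE)
  ann <- if (is.null(annotations)) emptyAnnotations() else annotations
  out <- lapply(seq_along(seqs), function(i)
    ProteinRecord(ids[i], as.character(seqs[[i]]), ann))
  names(out) <- ids
  out
}

#' Write proteins to a FASTA file
#'
#' @param proteins a [ProteinRecord-class] or list of them.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeProteinFasta <- function(proteins, path) {
  if (is(proteins, "ProteinRecord")) proteins <- list(proteins)
  set <- Biostrings::AAStringSet(vapply(proteins, proteinSequence, ""))
  names(set) <- vapply(proteins, proteinId, "")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}

#' Read a structural annotation track
#'
#' TSV with columns `name`, `start`, `end`, `kind`; coordinates 1-based
#' inclusive, `kind` one of `domain`, `helix`, `loop`, `residue`.
#'
#' @param path TSV file.
#' @return annotation `data.frame`.
#' @export
readAnnotationTrack <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(tab, c("name", "start", "end", "kind"), path)
  bad <- setdiff(unique(tab$kind), ANNOTATION_KINDS)
  if (length(bad))
    stop(sprintf("file '%s': unknown annotation kind(s): %s", path,
                 paste(bad, collapse = ", ")), call. = FALSE)
  tab
}

#' Read a DARTS identification-score table
#'
#' TSV with columns `replicate_id`, `condition`, `dose_uM` (empty for
#' controls), `protein_id`, `score`; see [computeProtection()] for the
#' condition labels.
#'
#' @param path TSV file.
#' @return validated long-format `data.frame`.
#' @export
readIdentificationTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(tab, c("replicate_id", "condition", "dose_uM",
                        "protein_id", "score"), path)
  tab$dose_uM <- as.numeric(tab$dose_uM)
  checkIdentificationTable(tab)
  tab
}

#' Read an MRM peak-area table
#'
#' TSV with columns `peptide_id`, `transition_id`, `condition`, `dose_uM`,
#' `replicate_id`, `area`; see [rollupPeptide()] for the condition labels.
#'
#' @param path TSV file.
#' @return validated long-format `data.frame`.
#' @export
readPeakAreaTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(tab, c("peptide_id", "transition_id", "condition",
                        "dose_uM", "replicate_id", "area"), path)
  tab$dose_uM <- as.numeric(tab$dose_uM)
  checkAreaTable(tab)
  tab
}

#' Read chromatogram traces in long form
#'
#' TSV with columns `peptide_id`, `transition_id`, `condition`, `dose_uM`,
#' `replicate_id`, `time_min`, `intensity`.
#'
#' @param path TSV file.
#' @return `data.frame`.
#' @export
readChromTraces <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  requireColumns(tab, c("peptide_id", "transition_id", "condition",
                        "dose_uM", "replicate_id", "time_min",
                        "intensity"), path)
  tab
}

#' Read a dose-response viability table
#'
#' CSV with columns `concentration_uM`, `T`, `T0`, `C`, `replicate_id`.
#'
#' @param path CSV file.
#' @return `data.frame`.
#' @export
readDoseResponseTable <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE)
  requireColumns(tab, c("concentration_uM", "T", "T0", "C",
                        "replicate_id"), path)
  tab
}

#' Write a DARTS target-ranking report (TSV + JSON with Venn partition)
#'
#' @param ranking output of [rankTargets()].
#' @param venn output of [intersectReplicates()].
#' @param prefix output path prefix; writes `<prefix>.tsv` and
#'   `<prefix>.json`.
#' @return the two paths, invisibly.
#' @export
writeRankingReport <- function(ranking, venn, prefix) {
  tsv <- paste0(prefix, ".tsv"); js <- paste0(prefix, ".json")
  write.table(ranking, tsv, sep = "\t", quote = FALSE, row.names = FALSE)
  jsonlite::write_json(
    list(ranking = ranking, intersection = venn$intersection,
         venn = as.list(venn$venn)),
    js, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(tsv, js))
}

#' Summarise a t-LiP experiment per peptide
#'
#' One row per quantified peptide, mirroring the usual targeted-MRM
#' summary layout: sequence and location, peptide length, doubly charged
#' precursor m/z, most intense monitored daughter (longest y-ion) m/z,
#' per-dose fold changes with their p-values, and the LiP-selection
#' p-value (both contrasts are reported).
#'
#' @param peptides peptide coordinate map (`peptide_id`, `sequence`,
#'   `start`, `end`), e.g. from [simulateTlipAreas()].
#' @param lip output of [selectLipPeptides()].
#' @param fcs output of [foldChange()].
#' @param protectedIds peptide ids called protected
#'   (e.g. [callProtected()]); flagged in the output.
#' @return `data.frame`, one row per peptide.
#' @export
tlipSummary <- function(peptides, lip, fcs, protectedIds = character()) {
  doses <- sort(unique(fcs$dose_uM))
  rows <- lapply(seq_len(nrow(peptides)), function(i) {
    p <- peptides[i, ]
    frags <- fragmentIons(p$sequence)
    y <- frags[frags$series == "y", ]
    row <- data.frame(
      peptide_id = p$peptide_id, sequence = p$sequence,
      start = p$start, end = p$end, length = nchar(p$sequence),
      precursor_mz_2plus = precursorMz(peptideMass(p$sequence), 2L),
      daughter_mz = max(y$mz[y$index == max(y$index)]),
      stringsAsFactors = FALSE)
    li <- lip[lip$peptide_id == p$peptide_id, ]
    row$is_lip <- if (nrow(li)) li$is_lip[1] else NA
    row$p_lip <- if (nrow(li)) li$p_value[1] else NA_real_
    for (d in doses) {
      f <- fcs[fcs$peptide_id == p$peptide_id & fcs$dose_uM == d, ]
      row[[sprintf("fc_%guM", d)]] <- if (nrow(f)) f$fc[1] else NA_real_
      row[[sprintf("p_fc_%guM", d)]] <- if (nrow(f)) f$p_value[1]
                                        else NA_real_
    }
    row$protected <- p$peptide_id %in% protectedIds
    row
  })
  out <- do.call(rbind, rows)
  out[order(out$start, out$end), , drop = FALSE]
}

#' Write a region report as JSON and a markdown table
#'
#' @param report a [RegionReport-class].
#' @param prefix output path prefix; writes `<prefix>.json` and
#'   `<prefix>.md`.
#' @param summary optional [tlipSummary()] table included in both outputs.
#' @return the two paths, invisibly.
#' @export
writeRegionReport <- function(report, prefix, summary = NULL) {
  js <- paste0(prefix, ".json"); md <- paste0(prefix, ".md")
  payload <- list(protein_id = report@protein_id,
                  protected_intervals = report@intervals,
                  annotation_overlaps = report@overlaps)
  if (!is.null(summary)) payload$peptide_summary <- summary
  jsonlite::write_json(payload, js, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  lines <- c(sprintf("# Protected regions of %s", report@protein_id), "",
             "Coordinates are 1-based inclusive residue positions.", "")
  if (nrow(report@intervals))
    lines <- c(lines, "## Merged protected intervals", "",
               sprintf("- %d-%d", report@intervals$start,
                       report@intervals$end), "")
  if (nrow(report@overlaps)) {
    lines <- c(lines, "## Annotation overlaps", "",
               "| interval | annotation | kind | overlap (residues) |",
               "|---|---|---|---|",
               sprintf("| %d-%d | %s | %s | %d |",
                       report@overlaps$start, report@overlaps$end,
                       report@overlaps$name, report@overlaps$kind,
                       report@overlaps$overlap_length), "")
  }
  if (!is.null(summary)) {
    cols <- names(summary)
    lines <- c(lines, "## Peptide summary", "",
               paste0("| ", paste(cols, collapse = " | "), " |"),
               paste0("|", paste(rep("---", length(cols)),
                                 collapse = "|"), "|"),
               vapply(seq_len(nrow(summary)), function(i)
                 paste0("| ", paste(vapply(summary[i, ], function(v)
                   if (is.numeric(v)) sprintf("%.5g", v)
                   else as.character(v), ""), collapse = " | "), " |"),
                 ""))
  }
  writeLines(lines, md)
  invisible(c(js, md))
}
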