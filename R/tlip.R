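## t-LiP-MRM analysis. A native lysate is nicked by subtilisin (limited
## proteolysis), then denatured and fully digested by trypsin; fully
## tryptic peptide areas measured by MRM drop wherever subtilisin could
## cut. Peptides whose area is significantly lower in the double digest
## than in the trypsin-only control are "LiP peptides"; a ligand that
## shields a region raises those areas back up, read out as a fold change
## over the vehicle. Protected peptides are merged and mapped onto the
## protein's structural annotation track.

TLIP_CONDITIONS <- c("trypsin_only", "double_digest_vehicle",
                     "double_digest_dose")

checkAreaTable <- function(areas) {
  need <- c("peptide_id", "transition_id", "condition", "dose_uM",
            "replicate_id", "area")
  miss <- setdiff(need, names(areas))
  if (length(miss))
    stop(sprintf("peak area table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(areas$condition), TLIP_CONDITIONS)
  if (length(bad))
    stop(sprintf("unknown condition label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(TLIP_CONDITIONS, collapse = ", ")), call. = FALSE)
  if (any(areas$area < 0, na.rm = TRUE))
    stop("areas must be non-negative", call. = FALSE)
  invisible(TRUE)
}

#' Integrate a chromatographic peak
#'
#' Trapezoidal integration of an intensity trace over a retention-time
#' window, with optional linear baseline drawn between the trace values at
#' the window endpoints. The integrand (intensity minus baseline) is
#' floored at zero pointwise.
#'
#' @param time retention times in minutes, strictly increasing.
#' @param intensity intensities (same length as `time`).
#' @param window numeric `c(t0, t1)` with `t0 < t1`, inside the trace's
#'   time range.
#' @param baseline `"none"` (default) or `"linear_endpoints"`.
#' @return the peak area (intensity x minutes).
#' @export
integratePeak <- function(time, intensity, window,
                          baseline = c("none", "linear_endpoints")) {
  baseline <- match.arg(baseline)
  if (length(time) != length(intensity))
    stop("time and intensity must have equal length", call. = FALSE)
  if (any(diff(time) <= 0))
    stop("time must be strictly increasing", call. = FALSE)
  t0 <- window[1]; t1 <- window[2]
  if (!(t0 < t1)) stop("window must satisfy t0 < t1", call. = FALSE)
  if (t0 < min(time) || t1 > max(time))
    stop(sprintf("window [%g, %g] outside trace time range [%g, %g]",
                 t0, t1, min(time), max(time)), call. = FALSE)
  inside <- time > t0 & time < t1
  tt <- c(t0, time[inside], t1)
  yy <- approx(time, intensity, xout = tt)$y
  base <- if (baseline == "none") 0
          else approx(c(t0, t1), yy[c(1L, length(yy))], xout = tt)$y
  pracma::trapz(tt, pmax(yy - base, 0))
}

#' Roll transition areas up to peptide level
#'
#' @param areas long-format area table with columns `peptide_id`,
#'   `transition_id`, `condition`, `dose_uM`, `replicate_id`, `area`.
#' @param method `"sum"` (default, common MRM practice) or `"mean"`.
#' @return area table with one row per (peptide, condition, dose,
#'   replicate); `transition_id` is dropped.
#' @export
rollupPeptide <- function(areas, method = c("sum", "mean")) {
  method <- match.arg(method)
  checkAreaTable(areas)
  f <- if (method == "sum") sum else mean
  doseKey <- ifelse(is.na(areas$dose_uM), "", as.character(areas$dose_uM))
  key <- paste(areas$peptide_id, areas$condition, doseKey,
               areas$replicate_id, sep = "\r")
  agg <- tapply(areas$area, key, f)
  parts <- strsplit(names(agg), "\r", fixed = TRUE)
  dose <- vapply(parts, `[`, "", 3L)
  out <- data.frame(
    peptide_id = vapply(parts, `[`, "", 1L),
    condition = vapply(parts, `[`, "", 2L),
    dose_uM = ifelse(dose == "", NA_real_, as.numeric(dose)),
    replicate_id = vapply(parts, `[`, "", 4L),
    area = as.numeric(agg), stringsAsFactors = FALSE)
  out <- out[order(out$peptide_id, out$condition, out$dose_uM,
                   out$replicate_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

## zero areas are not usable on a log scale; impute half the smallest
## positive area in the table (standard proteomics floor), with a warning
floorZeroAreas <- function(areas) {
  zero <- areas$area == 0
  if (any(zero)) {
    pos <- areas$area[areas$area > 0]
    if (!length(pos))
      stop("all areas are zero; nothing to analyse", call. = FALSE)
    floorVal <- min(pos) / 2
    warning(sprintf("%d zero area(s) floored at %.4g (half the smallest positive area)",
                    sum(zero), floorVal))
    areas$area[zero] <- floorVal
  }
  areas
}

## Welch t-test on log2 areas; degenerate (both groups constant) cases get
## p = 0 when separated in the tested direction, 1 otherwise, so that
## noise-free data behave as the limit of vanishing noise
welchLog2 <- function(x, y, alternative) {
  if (length(x) < 2L || length(y) < 2L) return(NA_real_)
  lx <- log2(x); ly <- log2(y)
  if (sd(lx) == 0 && sd(ly) == 0) {
    d <- mean(lx) - mean(ly)
    return(switch(alternative,
                  two.sided = if (d == 0) 1 else 0,
                  less = if (d < 0) 0 else 1,
                  greater = if (d > 0) 0 else 1))
  }
  t.test(lx, ly, alternative = alternative)$p.value
}

#' Select subtilisin-sensitive (LiP) peptides
#'
#' A peptide is a LiP peptide when its area in the double-digest vehicle
#' (negative control) is significantly lower than in the trypsin-only
#' digest (positive control): one-sided Welch t-test on log2 areas at
#' level `alpha`, and mean ratio below 1. Only LiP peptides carry a
#' conformational signal, so downstream protection calls are gated on this
#' selection.
#'
#' @param areas transition- or peptide-level area table; transitions are
#'   rolled up with [rollupPeptide()] first.
#' @param alpha significance level (default 0.05).
#' @param test `"welch"` (default) or `"wilcox"` (Mann-Whitney).
#' @param rollup rollup method passed to [rollupPeptide()].
#' @return `data.frame` per peptide: `peptide_id`, `mean_ratio_dd_vs_tryp`,
#'   `p_value`, `is_lip`.
#' @export
selectLipPeptides <- function(areas, alpha = 0.05,
                              test = c("welch", "wilcox"),
                              rollup = "sum") {
  test <- match.arg(test)
  pep <- if ("transition_id" %in% names(areas))
    rollupPeptide(areas, rollup) else areas
  pep <- floorZeroAreas(pep)
  tryp <- pep[pep$condition == "trypsin_only", , drop = FALSE]
  veh <- pep[pep$condition == "double_digest_vehicle", , drop = FALSE]
  peptides <- sort(intersect(unique(tryp$peptide_id),
                             unique(veh$peptide_id)))
  rows <- lapply(peptides, function(p) {
    x <- tryp$area[tryp$peptide_id == p]
    y <- veh$area[veh$peptide_id == p]
    if (length(x) < 2L || length(y) < 2L)
      stop(sprintf("peptide '%s': need >= 2 replicates per condition",
                   p), call. = FALSE)
    ratio <- mean(y) / mean(x)
    pval <- if (test == "welch") welchLog2(y, x, "less")
            else suppressWarnings(
              stats::wilcox.test(y, x, alternative = "less")$p.value)
    data.frame(peptide_id = p, mean_ratio_dd_vs_tryp = ratio,
               p_value = pval,
               is_lip = !is.na(pval) && pval <= alpha && ratio < 1,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Ligand fold changes of peptide areas
#'
#' For each peptide and dose within the double-digest arm:
#' `fc = mean(area | ligand dose) / mean(area | vehicle)`, means taken over
#' replicates, with a two-sided Welch t-test on log2 areas. Fold changes
#' above 1 on LiP peptides indicate ligand protection of that region.
#'
#' @inheritParams selectLipPeptides
#' @param peptideId optional single peptide to restrict to.
#' @param dose optional single dose (uM) to restrict to.
#' @return `data.frame`: `peptide_id`, `dose_uM`, `fc`, `p_value`.
#' @export
foldChange <- function(areas, peptideId = NULL, dose = NULL,
                       rollup = "sum") {
  pep <- if ("transition_id" %in% names(areas))
    rollupPeptide(areas, rollup) else areas
  pep <- floorZeroAreas(pep)
  veh <- pep[pep$condition == "double_digest_vehicle", , drop = FALSE]
  dosed <- pep[pep$condition == "double_digest_dose", , drop = FALSE]
  if (!is.null(peptideId)) {
    veh <- veh[veh$peptide_id %in% peptideId, , drop = FALSE]
    dosed <- dosed[dosed$peptide_id %in% peptideId, , drop = FALSE]
  }
  if (!is.null(dose)) dosed <- dosed[dosed$dose_uM %in% dose, , drop = FALSE]
  peptides <- sort(intersect(unique(veh$peptide_id),
                             unique(dosed$peptide_id)))
  doses <- sort(unique(dosed$dose_uM))
  rows <- list()
  for (p in peptides) {
    y0 <- veh$area[veh$peptide_id == p]
    if (mean(y0) == 0)
      stop(sprintf("peptide '%s': vehicle mean area is 0; fold change undefined", p),
           call. = FALSE)
    for (d in doses) {
      y1 <- dosed$area[dosed$peptide_id == p & dosed$dose_uM == d]
      if (!length(y1)) next
      rows[[length(rows) + 1L]] <- data.frame(
        peptide_id = p, dose_uM = d, fc = mean(y1) / mean(y0),
        p_value = welchLog2(y1, y0, "two.sided"),
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Call ligand-protected peptides
#'
#' A peptide is called protected when it is a LiP peptide (see
#' [selectLipPeptides()]) and shows `fc >= fcMin` with `p <= alpha` at one
#' or more doses. Non-LiP peptides are never called, whatever their fold
#' change: a region subtilisin cannot reach carries no conformational
#' signal.
#'
#' @param lip output of [selectLipPeptides()].
#' @param fcs output of [foldChange()].
#' @param fcMin fold-change threshold (default 1.5).
#' @param alpha significance level on the fold-change p-value
#'   (default 0.05).
#' @param adjust p-value adjustment method for the fold-change p-values
#'   (`"none"` by default; e.g. `"BH"` for Benjamini-Hochberg).
#' @return sorted character vector of protected peptide ids.
#' @export
callProtected <- function(lip, fcs, fcMin = 1.5, alpha = 0.05,
                          adjust = "none") {
  lipIds <- lip$peptide_id[lip$is_lip]
  p <- stats::p.adjust(fcs$p_value, method = adjust)
  hit <- fcs$peptide_id %in% lipIds & fcs$fc >= fcMin & !is.na(p) &
    p <= alpha
  sort(unique(fcs$peptide_id[hit]))
}

#' Run the full t-LiP-MRM inference chain
#'
#' Rolls transition areas up to peptides, selects LiP peptides against the
#' trypsin-only control, computes ligand fold changes, calls protected
#' peptides, and maps them onto the protein's annotation track.
#'
#' @inheritParams selectLipPeptides
#' @inheritParams callProtected
#' @param protein a [ProteinRecord-class].
#' @param peptides peptide coordinate map with columns `peptide_id`,
#'   `start`, `end` (and `sequence`, for reporting).
#' @return list with `lip`, `fcs`, `protected` (peptide ids) and `report`
#'   (a [RegionReport-class]).
#' @export
tlipPipeline <- function(areas, protein, peptides, alpha = 0.05,
                         fcMin = 1.5, test = "welch", rollup = "sum",
                         adjust = "none") {
  lip <- selectLipPeptides(areas, alpha = alpha, test = test,
                           rollup = rollup)
  fcs <- foldChange(areas, rollup = rollup)
  protected <- callProtected(lip, fcs, fcMin = fcMin, alpha = alpha,
                             adjust = adjust)
  coords <- peptides[peptides$peptide_id %in% protected, , drop = FALSE]
  report <- mapRegions(protein, coords)
  list(lip = lip, fcs = fcs, protected = protected, report = report)
}

#' RegionReport: merged protected intervals with annotation overlaps
#'
#' @slot protein_id protein identifier.
#' @slot intervals `data.frame` of merged protected residue intervals
#'   (`start`, `end`, 1-based inclusive; pairwise disjoint and sorted).
#' @slot overlaps `data.frame` of annotation overlaps: interval bounds,
#'   annotation `name`, `kind`, and `overlap_length` in residues.
#' @exportClass RegionReport
setClass("RegionReport",
  representation(protein_id = "character", intervals = "data.frame",
                 overlaps = "data.frame"))

setMethod("show", "RegionReport", function(object) {
  cat(sprintf("RegionReport for '%s': %d protected interval(s)\n",
              object@protein_id, nrow(object@intervals)))
  if (nrow(object@intervals))
    cat("  ", paste(sprintf("%d-%d", object@intervals$start,
                            object@intervals$end), collapse = ", "),
        "\n", sep = "")
  if (nrow(object@overlaps)) {
    cat(sprintf("  %d annotation overlap(s):\n", nrow(object@overlaps)))
    for (i in seq_len(min(nrow(object@overlaps), 10L)))
      cat(sprintf("    %d-%d ~ %s (%s, %d residue%s)\n",
                  object@overlaps$start[i], object@overlaps$end[i],
                  object@overlaps$name[i], object@overlaps$kind[i],
                  object@overlaps$overlap_length[i],
                  if (object@overlaps$overlap_length[i] > 1L) "s" else ""))
  }
})

#' @describeIn mapRegions merged protected intervals of a report.
#' @param report a `RegionReport`.
#' @export
protectedIntervals <- function(report) report@intervals

#' @describeIn mapRegions annotation overlaps of a report.
#' @export
regionOverlaps <- function(report) report@overlaps

#' Map protected peptides onto structural annotations
#'
#' Merges overlapping or bookended peptide intervals and intersects the
#' merged intervals with the protein's annotation track. Point
#' annotations (kind `residue`, e.g. a key tyrosine) are reported as hit
#' when they fall inside a merged interval.
#'
#' @param protein a [ProteinRecord-class] carrying the annotation track.
#' @param peptides `data.frame` with columns `start` and `end` (1-based
#'   inclusive residue intervals of the protected peptides).
#' @return a [RegionReport-class].
#' @export
mapRegions <- function(protein, peptides) {
  n <- proteinLength(protein)
  if (nrow(peptides) &&
      (any(peptides$start < 1L) || any(peptides$end > n) ||
       any(peptides$end < peptides$start)))
    stop(sprintf("peptide coordinates outside protein '%s' (1..%d)",
                 proteinId(protein), n), call. = FALSE)
  merged <- IRanges::reduce(IRanges::IRanges(peptides$start, peptides$end))
  intervals <- data.frame(start = BiocGenerics::start(merged),
                          end = BiocGenerics::end(merged))
  ann <- annotations(protein)
  overlaps <- data.frame(start = integer(), end = integer(),
                         name = character(), kind = character(),
                         overlap_start = integer(), overlap_end = integer(),
                         overlap_length = integer(),
                         stringsAsFactors = FALSE)
  if (nrow(ann) && length(merged)) {
    annR <- IRanges::IRanges(ann$start, ann$end)
    hits <- IRanges::findOverlaps(merged, annR)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits); s <- S4Vectors::subjectHits(hits)
      inter <- IRanges::pintersect(merged[q], annR[s])
      overlaps <- data.frame(
        start = BiocGenerics::start(merged)[q],
        end = BiocGenerics::end(merged)[q],
        name = ann$name[s], kind = ann$kind[s],
        overlap_start = BiocGenerics::start(inter),
        overlap_end = BiocGenerics::end(inter),
        overlap_length = BiocGenerics::width(inter),
        stringsAsFactors = FALSE)
      overlaps <- overlaps[order(overlaps$start, overlaps$overlap_start), ]
      rownames(overlaps) <- NULL
    }
  }
  new("RegionReport", protein_id = proteinId(protein),
      intervals = intervals, overlaps = overlaps)
}
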