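## DARTS target identification: ligand binding shields a target protein
## from limited proteolysis, so its identification score in a
## ligand-treated digested sample recovers toward the undigested control.
## Protection is normalised between the vehicle-digested (0%) and
## undigested (100%) controls of the same replicate:
##   protection = 100 * (S_dose - S_vehicle) / (S_undigested - S_vehicle)
## clipped to [0, 100]. Candidate targets are proteins protected in every
## replicate, ranked by mean protection.

DARTS_CONDITIONS <- c("undigested_control", "digested_vehicle",
                      "digested_dose")

checkIdentificationTable <- function(table) {
  need <- c("replicate_id", "condition", "dose_uM", "protein_id", "score")
  miss <- setdiff(need, names(table))
  if (length(miss))
    stop(sprintf("identification table lacks column(s): %s",
                 paste(miss, collapse = ", ")), call. = FALSE)
  bad <- setdiff(unique(table$condition), DARTS_CONDITIONS)
  if (length(bad))
    stop(sprintf("unknown condition label(s): %s (expected %s)",
                 paste(bad, collapse = ", "),
                 paste(DARTS_CONDITIONS, collapse = ", ")), call. = FALSE)
  if (any(table$score < 0, na.rm = TRUE))
    stop("identification scores must be non-negative", call. = FALSE)
  invisible(TRUE)
}

controlScore <- function(table, replicateId, proteinId, condition) {
  hit <- table$replicate_id == replicateId & table$protein_id == proteinId &
    table$condition == condition
  if (!any(hit)) NA_real_ else table$score[hit][1]
}

#' Protection percentage of one protein at one dose
#'
#' Normalised recovery of the identification score between the two
#' controls of a replicate: 0% at the vehicle-digested score, 100% at the
#' undigested score, clipped to that range. A protein absent from the dose
#' condition scores 0 (absence of identification is informative in DARTS).
#'
#' @param table long-format identification table with columns
#'   `replicate_id`, `condition` (`undigested_control`, `digested_vehicle`,
#'   `digested_dose`), `dose_uM` (NA for controls), `protein_id`, `score`.
#' @param proteinId protein to score.
#' @param dose ligand dose in uM (must appear in the table).
#' @param replicateId replicate to score.
#' @return one-row `data.frame`: `protein_id`, `replicate_id`, `dose_uM`,
#'   `protection` (percent in \[0, 100\]).
#' @export
computeProtection <- function(table, proteinId, dose, replicateId) {
  checkIdentificationTable(table)
  su <- controlScore(table, replicateId, proteinId, "undigested_control")
  sv <- controlScore(table, replicateId, proteinId, "digested_vehicle")
  if (is.na(su) || is.na(sv))
    stop(sprintf("protein '%s' missing from a control condition of replicate '%s'",
                 proteinId, replicateId), call. = FALSE)
  if (su <= sv)
    stop(sprintf(
      "degenerate controls for protein '%s' in replicate '%s': undigested score (%.3g) <= vehicle score (%.3g); protection undefined",
      proteinId, replicateId, su, sv), call. = FALSE)
  hit <- table$replicate_id == replicateId & table$protein_id == proteinId &
    table$condition == "digested_dose" & table$dose_uM == dose
  sd <- if (any(hit)) table$score[hit][1] else 0
  prot <- 100 * (sd - sv) / (su - sv)
  data.frame(protein_id = proteinId, replicate_id = replicateId,
             dose_uM = dose, protection = min(max(prot, 0), 100),
             stringsAsFactors = FALSE)
}

#' All protection records of an identification table
#'
#' Vectorised [computeProtection()] over every (replicate, dose, protein)
#' combination. Proteins with degenerate controls (undigested score not
#' above vehicle) get `NA` protection with a warning; proteins absent from
#' a dose condition score 0.
#'
#' @inheritParams computeProtection
#' @return `data.frame` of protection records.
#' @export
protectionTable <- function(table) {
  checkIdentificationTable(table)
  out <- list()
  for (rep in unique(table$replicate_id)) {
    sub <- table[table$replicate_id == rep, , drop = FALSE]
    und <- sub[sub$condition == "undigested_control", , drop = FALSE]
    veh <- sub[sub$condition == "digested_vehicle", , drop = FALSE]
    dosed <- sub[sub$condition == "digested_dose", , drop = FALSE]
    prots <- intersect(und$protein_id, veh$protein_id)
    doses <- sort(unique(dosed$dose_uM))
    if (!length(prots) || !length(doses)) next
    su <- und$score[match(prots, und$protein_id)]
    sv <- veh$score[match(prots, veh$protein_id)]
    degenerate <- su <= sv
    if (any(degenerate))
      warning(sprintf("replicate '%s': %d protein(s) with undigested <= vehicle score; protection set NA",
                      rep, sum(degenerate)))
    for (d in doses) {
      dd <- dosed[dosed$dose_uM == d, , drop = FALSE]
      sd <- dd$score[match(prots, dd$protein_id)]
      sd[is.na(sd)] <- 0
      prot <- 100 * (sd - sv) / (su - sv)
      prot <- pmin(pmax(prot, 0), 100)
      prot[degenerate] <- NA_real_
      out[[length(out) + 1L]] <- data.frame(
        protein_id = prots, replicate_id = rep, dose_uM = d,
        protection = prot, stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

vennPattern <- function(members, replicates) {
  paste(replicates[members], collapse = "&")
}

#' Replicate intersection of protected proteins, with Venn partition
#'
#' A protein counts as protected in a replicate when its protection
#' exceeds `floor` at one or more doses. The intersection keeps proteins
#' protected in every replicate; the Venn partition gives the count of
#' proteins in each replicate-subset cell (cells sum to the union size).
#'
#' @param records protection records from [protectionTable()] (or an
#'   identification table, which is converted first).
#' @param floor protection floor in percent (default 0: any positive
#'   protection).
#' @return list with `intersection` (character vector of protein ids),
#'   `venn` (named integer vector, names like `"rep1&rep3"`), and
#'   `protected` (list of per-replicate protected sets).
#' @export
intersectReplicates <- function(records, floor = 0) {
  if (!"protection" %in% names(records)) records <- protectionTable(records)
  reps <- sort(unique(records$replicate_id))
  if (length(reps) < 2L)
    stop("need at least 2 replicates to intersect", call. = FALSE)
  protected <- lapply(reps, function(r) {
    sub <- records[records$replicate_id == r & !is.na(records$protection), ]
    sort(unique(sub$protein_id[sub$protection > floor]))
  })
  names(protected) <- reps
  union_ <- sort(unique(unlist(protected)))
  membership <- vapply(protected, function(s) union_ %in% s,
                       logical(length(union_)))
  if (length(union_) == 1L) membership <- matrix(membership, nrow = 1L)
  patterns <- apply(membership, 1L, function(m)
    paste(reps[m], collapse = "&"))
  venn <- table(patterns)
  list(intersection = union_[rowSums(membership) == length(reps)],
       venn = setNames(as.integer(venn), names(venn)),
       protected = protected)
}

#' Rank candidate targets by mean protection
#'
#' Restricted to the replicate intersection; sorted by mean protection
#' across all replicates and doses (descending), ties broken by the number
#' of replicates in which the protein is protected, then by protein id
#' (lexicographic) for determinism. Per-dose mean protections are reported
#' alongside the pooled mean.
#'
#' @param records protection records from [protectionTable()].
#' @param intersection protein ids to rank (typically
#'   `intersectReplicates(...)$intersection`).
#' @param floor protection floor used for the per-replicate protected
#'   counts (default 0).
#' @return `data.frame` sorted by rank: `protein_id`, `mean_protection`
#'   (pooled across doses and replicates), `n_replicates_protected`,
#'   `doses_protected` (comma-joined), plus one `mean_at_<dose>` column per
#'   dose.
#' @export
rankTargets <- function(records, intersection, floor = 0) {
  if (!length(intersection)) {
    warning("empty intersection: no targets to rank")
    return(data.frame(protein_id = character(),
                      mean_protection = numeric(),
                      n_replicates_protected = integer(),
                      doses_protected = character(),
                      stringsAsFactors = FALSE))
  }
  sub <- records[records$protein_id %in% intersection &
                   !is.na(records$protection), , drop = FALSE]
  doses <- sort(unique(sub$dose_uM))
  rows <- lapply(sort(unique(sub$protein_id)), function(p) {
    ss <- sub[sub$protein_id == p, , drop = FALSE]
    byRep <- tapply(ss$protection, ss$replicate_id, function(x)
      any(x > floor))
    byDoseProt <- tapply(ss$protection, ss$dose_uM, function(x)
      any(x > floor))
    perDose <- vapply(doses, function(d)
      mean(ss$protection[ss$dose_uM == d]), numeric(1))
    row <- data.frame(protein_id = p,
                      mean_protection = mean(ss$protection),
                      n_replicates_protected = sum(byRep, na.rm = TRUE),
                      doses_protected = paste(
                        names(byDoseProt)[which(byDoseProt)],
                        collapse = ","),
                      stringsAsFactors = FALSE)
    for (i in seq_along(doses))
      row[[paste0("mean_at_", doses[i])]] <- perDose[i]
    row
  })
  out <- do.call(rbind, rows)
  out <- out[order(-out$mean_protection, -out$n_replicates_protected,
                   out$protein_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Loading-normalised densitometry trend across a dose series
#'
#' Band intensities are divided by the loading-control intensities; the
#' trend is flagged monotone when the normalised series increases with
#' dose (positive Spearman correlation) with no relative decrease larger
#' than `tolerance` between consecutive doses.
#'
#' @param band band intensities (arbitrary units, > 0), in dose order.
#' @param loading loading-control intensities (same length, > 0).
#' @param doses dose values in the same order.
#' @param tolerance largest tolerated relative decrease between
#'   consecutive normalised intensities (default 0.05).
#' @return list with `normalized`, `monotone` (logical) and `rho`
#'   (Spearman correlation with dose).
#' @export
densitometryTrend <- function(band, loading, doses, tolerance = 0.05) {
  if (length(band) != length(loading) || length(band) != length(doses))
    stop("band, loading and doses must have equal length", call. = FALSE)
  if (any(loading <= 0))
    stop("loading intensities must be positive (division guard)",
         call. = FALSE)
  if (any(band <= 0))
    stop("band intensities must be positive", call. = FALSE)
  norm <- band / loading
  ord <- order(doses)
  normOrd <- norm[ord]
  rho <- suppressWarnings(cor(doses, norm, method = "spearman"))
  drops <- diff(normOrd) / normOrd[-length(normOrd)]
  monotone <- !is.na(rho) && rho > 0 && all(drops >= -tolerance)
  list(normalized = norm, monotone = monotone, rho = rho)
}
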