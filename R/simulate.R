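## Seeded synthetic-data generators with planted ground truth. Every
## generator is a pure function of its arguments (same seed, identical
## output) and returns the truth alongside the data, so each pipeline
## stage can be tested against what was planted. Identification scores and
## peak areas carry multiplicative log-normal noise parameterised by a
## coefficient of variation, the standard model for MS intensity data.

## log-normal multiplier with mean 1 and coefficient of variation cv
lnNoise <- function(n, cv) {
  if (cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

## glycogen-phosphorylase-like structural features; verbatim when the
## sequence is long enough to hold them, otherwise scaled proportionally
defaultAnnotationTrack <- function(n) {
  ann <- data.frame(
    name = c("N_domain", "C_domain", "cap_loop", "helix_2",
             "beta4_beta5_loop", "tower_helices", "gate_loop",
             "Tyr75", "Tyr196"),
    start = c(22L, 485L, 41L, 49L, 180L, 259L, 279L, 75L, 196L),
    end = c(484L, 822L, 48L, 77L, 198L, 278L, 289L, 75L, 196L),
    kind = c("domain", "domain", "loop", "helix", "loop", "helix", "loop",
             "residue", "residue"),
    stringsAsFactors = FALSE)
  if (n < 823L) {
    f <- n / 823
    ann$start <- pmax(1L, as.integer(round(ann$start * f)))
    ann$end <- pmin(n, pmax(ann$start, as.integer(round(ann$end * f))))
  }
  ann
}

#' Generate a random protein with a glycogen-phosphorylase-like
#' annotation track
#'
#' A seeded random sequence over the 20-letter alphabet with K+R frequency
#' near 11% (the tryptic-site density of real proteomes), carrying a
#' default structural annotation track (two domains, dimer-interface
#' helices and loops, the gate loop, and two key tyrosines, forced to Y in
#' the sequence). When the protein is at least 823 residues the intervals
#' are used verbatim; shorter proteins get them scaled proportionally.
#'
#' @param seed RNG seed.
#' @param length protein length in residues (>= 50; default 900).
#' @param id protein identifier.
#' @return a [ProteinRecord-class].
#' @export
makeProtein <- function(seed, length = 900L, id = "SYNPYGB") {
  if (length < 50L) stop("protein length must be >= 50", call. = FALSE)
  set.seed(seed)
  krFreq <- 0.11
  w <- setNames(rep((1 - krFreq) / 18, 20L), AA20)
  w[c("K", "R")] <- krFreq / 2
  letters <- sample(AA20, length, replace = TRUE, prob = w)
  ann <- defaultAnnotationTrack(length)
  keyRes <- ann[ann$kind == "residue", ]
  letters[keyRes$start] <- "Y"
  ProteinRecord(id, paste(letters, collapse = ""), ann)
}

#' Simulate DARTS identification-score tables with a planted target
#'
#' Emulates a limited-proteolysis target-identification experiment: per
#' replicate, undigested-control scores are log-normal; vehicle-digested
#' scores are the undigested scores times a digestion-survival fraction;
#' dose scores interpolate from the vehicle toward the undigested score so
#' that the noiseless protection equals the planted percentage — rising
#' with dose for target proteins, a low constant drawn uniformly from
#' `backgroundRange` for the rest. All scores then receive multiplicative
#' log-normal noise.
#'
#' @param seed RNG seed.
#' @param nProteins number of identified proteins (default 300).
#' @param nTargets number of planted targets protected in every replicate
#'   (default 3, seeded choice of ids).
#' @param doses ligand doses in uM (default `c(1, 10, 100)`).
#' @param targetProtection planted target protection percent per dose
#'   (default `c(40, 60, 80)`, one value per dose).
#' @param backgroundRange range of background protection percent
#'   (default `c(0, 10)`).
#' @param survival digestion-survival score fraction of the vehicle
#'   control (default 0.25).
#' @param noiseCv coefficient of variation of the score noise
#'   (default 0.15).
#' @param nReplicates number of replicates (default 3).
#' @return list with `tables` (long identification table, see
#'   [computeProtection()]) and `truth` (planted target ids, per-dose
#'   target protection, per-protein background protection).
#' @export
simulateDartsTables <- function(seed, nProteins = 300L, nTargets = 3L,
                                doses = c(1, 10, 100),
                                targetProtection = c(40, 60, 80),
                                backgroundRange = c(0, 10),
                                survival = 0.25, noiseCv = 0.15,
                                nReplicates = 3L) {
  if (length(targetProtection) != length(doses))
    stop("targetProtection must have one value per dose", call. = FALSE)
  set.seed(seed)
  prots <- sprintf("prot%04d", seq_len(nProteins))
  targets <- sort(sample(prots, nTargets))
  baseline <- rlnorm(nProteins, meanlog = log(1000), sdlog = 0.4)
  background <- runif(nProteins, backgroundRange[1], backgroundRange[2])
  names(background) <- prots
  background[targets] <- NA_real_   # targets follow targetProtection
  rows <- list()
  for (r in seq_len(nReplicates)) {
    rep_id <- sprintf("rep%d", r)
    u0 <- baseline
    v0 <- baseline * survival
    rows[[length(rows) + 1L]] <- data.frame(
      replicate_id = rep_id, condition = "undigested_control",
      dose_uM = NA_real_, protein_id = prots,
      score = u0 * lnNoise(nProteins, noiseCv), stringsAsFactors = FALSE)
    rows[[length(rows) + 1L]] <- data.frame(
      replicate_id = rep_id, condition = "digested_vehicle",
      dose_uM = NA_real_, protein_id = prots,
      score = v0 * lnNoise(nProteins, noiseCv), stringsAsFactors = FALSE)
    for (j in seq_along(doses)) {
      p <- ifelse(prots %in% targets, targetProtection[j], background)
      s0 <- v0 + p / 100 * (u0 - v0)
      rows[[length(rows) + 1L]] <- data.frame(
        replicate_id = rep_id, condition = "digested_dose",
        dose_uM = doses[j], protein_id = prots,
        score = s0 * lnNoise(nProteins, noiseCv), stringsAsFactors = FALSE)
    }
  }
  tables <- do.call(rbind, rows)
  rownames(tables) <- NULL
  list(tables = tables,
       truth = list(target_ids = targets, doses = doses,
                    target_protection = targetProtection,
                    background_protection = background[!prots %in% targets],
                    survival = survival, noise_cv = noiseCv,
                    n_replicates = nReplicates))
}

## quantifiable = fully tryptic, 0 missed cleavages, length within bounds
quantifiablePeptides <- function(protein, minLen, maxLen) {
  peps <- digestTryptic(protein, maxMissed = 0L)
  len <- peps$end - peps$start + 1L
  peps[len >= minLen & len <= maxLen, , drop = FALSE]
}

## snap a residue interval to the nearest quantifiable peptide (largest
## overlap, or smallest gap when nothing overlaps); only fully tryptic
## peptides are measurable by the targeted double-digestion design
snapInterval <- function(interval, peps) {
  if (!nrow(peps))
    stop(sprintf("planted interval %d-%d: protein has no quantifiable tryptic peptide",
                 interval[1], interval[2]), call. = FALSE)
  ov <- pmin(peps$end, interval[2]) - pmax(peps$start, interval[1]) + 1L
  peps[which.max(ov), , drop = FALSE]   # negative overlap = -(gap) - 1
}

#' Simulate a four-condition t-LiP-MRM peak-area table with planted
#' protection
#'
#' Emulates the targeted limited-proteolysis design: trypsin-only control,
#' double-digest vehicle, and double-digest plus ligand at each dose.
#' Planted protected intervals are snapped to the quantifiable fully
#' tryptic peptide with the largest overlap (the realised truth is
#' returned). Those peptides — plus a seeded fraction of decoy LiP
#' peptides elsewhere — have their double-digest areas suppressed by
#' `lipSuppression`; ligand doses multiply the planted (not decoy) peptide
#' areas by `protectionFc`. Transition-level areas split each peptide area
#' over fixed fragment weights, and every area receives multiplicative
#' log-normal noise.
#'
#' @param seed RNG seed.
#' @param protein a [ProteinRecord-class] (default: `makeProtein(seed)`).
#' @param intervals planted protected intervals, `data.frame` or matrix
#'   with columns start/end (default: the glycogen-phosphorylase-like
#'   trio `71-78`, `193-206`, `279-290`).
#' @param lipSuppression double-digest/trypsin-only area ratio of LiP
#'   peptides (default 0.2).
#' @param protectionFc planted ligand fold change (default 2).
#' @param noiseCv area noise coefficient of variation (default 0.10).
#' @param nReplicates replicates per condition (default 3).
#' @param doses ligand doses in uM (default `c(1, 10)`).
#' @param decoyLipFraction fraction of non-planted quantifiable peptides
#'   that are LiP (subtilisin-sensitive) without ligand response
#'   (default 0.2).
#' @param nTransitions transitions per peptide (default 3).
#' @param minLen,maxLen quantifiable peptide length bounds (defaults 6
#'   and 25).
#' @return list with `areas` (long transition-level table, see
#'   [rollupPeptide()]), `peptides` (peptide id to coordinate map) and
#'   `truth` (snapped intervals, planted and decoy peptide ids, planted
#'   fold change and suppression).
#' @export
simulateTlipAreas <- function(seed, protein = NULL,
                              intervals = data.frame(
                                start = c(71L, 193L, 279L),
                                end = c(78L, 206L, 290L)),
                              lipSuppression = 0.2, protectionFc = 2,
                              noiseCv = 0.10, nReplicates = 3L,
                              doses = c(1, 10), decoyLipFraction = 0.2,
                              nTransitions = 3L, minLen = 6L,
                              maxLen = 25L) {
  if (is.null(protein)) protein <- makeProtein(seed)
  set.seed(seed)
  intervals <- as.data.frame(intervals)
  peps <- quantifiablePeptides(protein, minLen, maxLen)
  if (!nrow(peps)) stop("no quantifiable peptides", call. = FALSE)
  snapped <- do.call(rbind, lapply(seq_len(nrow(intervals)), function(i)
    snapInterval(c(intervals$start[i], intervals$end[i]), peps)))
  snapped <- unique(snapped)
  pepId <- function(p) sprintf("pep_%04d_%04d", p$start, p$end)
  peps$peptide_id <- pepId(peps)
  plantedIds <- pepId(snapped)
  others <- setdiff(peps$peptide_id, plantedIds)
  decoyIds <- sort(sample(others, floor(decoyLipFraction * length(others))))
  lipIds <- c(plantedIds, decoyIds)
  nPep <- nrow(peps)
  abundance <- rlnorm(nPep, meanlog = log(1e5), sdlog = 0.5)
  w <- c(0.5, 0.3, 0.2, rep(0.1, max(0L, nTransitions - 3L)))[
    seq_len(nTransitions)]
  w <- w / sum(w)
  conditions <- rbind(
    data.frame(condition = "trypsin_only", dose_uM = NA_real_),
    data.frame(condition = "double_digest_vehicle", dose_uM = NA_real_),
    data.frame(condition = "double_digest_dose", dose_uM = doses))
  rows <- list()
  for (ci in seq_len(nrow(conditions))) {
    cond <- conditions$condition[ci]; d <- conditions$dose_uM[ci]
    scale <- rep(1, nPep)
    isLip <- peps$peptide_id %in% lipIds
    if (cond != "trypsin_only") scale[isLip] <- lipSuppression
    if (cond == "double_digest_dose")
      scale[peps$peptide_id %in% plantedIds] <-
        lipSuppression * protectionFc
    for (r in seq_len(nReplicates)) {
      for (t in seq_len(nTransitions)) {
        rows[[length(rows) + 1L]] <- data.frame(
          peptide_id = peps$peptide_id,
          transition_id = sprintf("y%d", t),
          condition = cond, dose_uM = d,
          replicate_id = sprintf("rep%d", r),
          area = abundance * w[t] * scale * lnNoise(nPep, noiseCv),
          stringsAsFactors = FALSE)
      }
    }
  }
  areas <- do.call(rbind, rows)
  rownames(areas) <- NULL
  list(areas = areas,
       peptides = peps[, c("peptide_id", "protein_id", "start", "end",
                           "sequence")],
       truth = list(
         requested_intervals = intervals,
         snapped_intervals = data.frame(start = snapped$start,
                                        end = snapped$end),
         planted_peptide_ids = sort(plantedIds),
         decoy_lip_peptide_ids = decoyIds,
         protection_fc = protectionFc, lip_suppression = lipSuppression,
         doses = doses, noise_cv = noiseCv))
}

#' Render a Gaussian chromatographic peak of known area
#'
#' @param area analytic peak area (intensity x minutes).
#' @param center peak apex retention time in minutes.
#' @param width Gaussian standard deviation in minutes (default 0.05).
#' @param from,to,by sampling grid in minutes (defaults cover +/- 6 sd at
#'   width/10 steps).
#' @return `data.frame` with `time_min` and `intensity`.
#' @export
gaussianTrace <- function(area, center, width = 0.05,
                          from = center - 6 * width,
                          to = center + 6 * width, by = width / 10) {
  t <- seq(from, to, by = by)
  data.frame(time_min = t,
             intensity = area * stats::dnorm(t, center, width))
}

#' Simulate a dose-response viability table with known GI50
#'
#' Percent growth follows a four-parameter logistic in log10 dose
#' (top 100, bottom 0 by default) with additive Gaussian noise in
#' percentage points, converted back to raw (T, T0, C) signal triplets
#' with fixed time-zero and control signals.
#'
#' @param seed RNG seed.
#' @param gi50 true GI50 in uM (default 17, a typical mid-range potency).
#' @param hill true Hill slope (default 1).
#' @param doses dose series in uM (default 8 log-spaced doses from 0.1 to
#'   200, the usual screening range).
#' @param noiseSd Gaussian noise on percent growth, in percentage points
#'   (default 5).
#' @param nReplicates replicates per dose (default 3).
#' @param t0Signal,controlSignal raw time-zero and vehicle-control signals
#'   (defaults 0.2 and 1.2 absorbance units).
#' @return list with `data` (`concentration_uM`, `T`, `T0`, `C`,
#'   `replicate_id`) and `truth` (`gi50`, `hill`).
#' @export
simulateDoseResponse <- function(seed, gi50 = 17, hill = 1,
                                 doses = 10 ^ seq(log10(0.1), log10(200),
                                                  length.out = 8),
                                 noiseSd = 5, nReplicates = 3L,
                                 t0Signal = 0.2, controlSignal = 1.2) {
  set.seed(seed)
  rows <- list()
  for (r in seq_len(nReplicates)) {
    g <- fourPL(log10(doses), top = 100, bottom = 0,
                logMid = log10(gi50), hill = hill) +
      rnorm(length(doses), 0, noiseSd)
    rows[[length(rows) + 1L]] <- data.frame(
      concentration_uM = doses,
      T = t0Signal + g / 100 * (controlSignal - t0Signal),
      T0 = t0Signal, C = controlSignal,
      replicate_id = sprintf("rep%d", r), stringsAsFactors = FALSE)
  }
  data <- do.call(rbind, rows)
  rownames(data) <- NULL
  list(data = data, truth = list(gi50 = gi50, hill = hill))
}
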