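## compact builder for peptide-level area tables
areaRows <- function(peptide, condition, areas, dose = NA_real_,
                     transition = "y1") {
  data.frame(peptide_id = peptide, transition_id = transition,
             condition = condition, dose_uM = dose,
             replicate_id = sprintf("rep%d", seq_along(areas)),
             area = areas, stringsAsFactors = FALSE)
}

test_that("peak integration recovers simple and analytic areas", {
  # rectangular pulse of height h and width w
  t <- seq(0, 10, by = 0.01)
  h <- 250
  y <- ifelse(t >= 2 & t <= 5, h, 0)
  expect_equal(integratePeak(t, y, c(2, 5)), h * 3, tolerance = 1e-6)
  # exactly linear trace with endpoint baseline integrates to 0
  y2 <- 3 + 2 * t
  expect_equal(integratePeak(t, y2, c(1, 9), "linear_endpoints"), 0)
  # Gaussian peak of known analytic area, default sampling
  tr <- gaussianTrace(1234.5, center = 5, width = 0.05)
  got <- integratePeak(tr$time_min, tr$intensity,
                       c(5 - 4 * 0.05, 5 + 4 * 0.05))
  expect_lt(abs(got - 1234.5) / 1234.5, 0.01)
  expect_error(integratePeak(t, y, c(-1, 5)), "outside")
  expect_error(integratePeak(t, y, c(5, 2)), "t0 < t1")
  expect_error(integratePeak(c(1, 1, 2), c(0, 0, 0), c(1, 2)),
               "increasing")
})

test_that("peptide rollup sums transitions and is permutation-invariant", {
  tab <- data.frame(peptide_id = "pep1", transition_id = c("y1", "y2", "y3"),
                    condition = "trypsin_only", dose_uM = NA_real_,
                    replicate_id = "rep1", area = c(100, 200, 300))
  expect_equal(rollupPeptide(tab)$area, 600)
  expect_equal(rollupPeptide(tab, "mean")$area, 200)
  expect_equal(rollupPeptide(tab[c(3, 1, 2), ]), rollupPeptide(tab))
  # single transition is the identity
  expect_equal(rollupPeptide(tab[1, ])$area, 100)
  # NA doses of control conditions are preserved, not dropped
  expect_true(is.na(rollupPeptide(tab)$dose_uM))
})

test_that("LiP selection requires a significant drop in the double digest", {
  # identical areas: ratio 1, not selected
  same <- rbind(areaRows("p", "trypsin_only", c(100, 110, 90)),
                areaRows("p", "double_digest_vehicle", c(100, 110, 90)))
  sel <- selectLipPeptides(same)
  expect_false(sel$is_lip)
  expect_equal(sel$mean_ratio_dd_vs_tryp, 1)
  # strong suppression at low CV: selected with power ~ 1
  hits <- vapply(1:20, function(s) {
    set.seed(s)
    tryp <- 1000 * exp(rnorm(3, 0, 0.05))
    dd <- 0.2 * 1000 * exp(rnorm(3, 0, 0.05))
    selectLipPeptides(rbind(
      areaRows("p", "trypsin_only", tryp),
      areaRows("p", "double_digest_vehicle", dd)))$is_lip
  }, logical(1))
  expect_gte(mean(hits), 0.95)
  # directionality: larger double-digest areas are never LiP
  up <- rbind(areaRows("p", "trypsin_only", c(100, 101, 99)),
              areaRows("p", "double_digest_vehicle", c(500, 510, 490)))
  expect_false(selectLipPeptides(up)$is_lip)
  expect_error(selectLipPeptides(rbind(
    areaRows("p", "trypsin_only", 100),
    areaRows("p", "double_digest_vehicle", c(90, 95)))), "2 replicates")
})

test_that("zero areas are floored at half the smallest positive area", {
  tab <- rbind(areaRows("p", "trypsin_only", c(100, 0, 90)),
               areaRows("p", "double_digest_vehicle", c(20, 18, 22)))
  expect_warning(sel <- selectLipPeptides(tab), "floored at 9")
  expect_true(is.finite(sel$p_value))
})

test_that("fold change is a ratio of replicate means with a Welch p-value", {
  veh <- areaRows("p", "double_digest_vehicle", c(900, 1000, 1100))
  same <- rbind(veh, areaRows("p", "double_digest_dose",
                              c(900, 1000, 1100), dose = 1))
  expect_equal(foldChange(same)$fc, 1)
  doubled <- rbind(veh, areaRows("p", "double_digest_dose",
                                 c(1800, 2000, 2200), dose = 1))
  expect_equal(foldChange(doubled)$fc, 2)
  # reciprocal identity: swapping the roles inverts the ratio
  swapped <- rbind(
    areaRows("p", "double_digest_vehicle", c(1800, 2000, 2200)),
    areaRows("p", "double_digest_dose", c(900, 1000, 1100), dose = 1))
  expect_equal(foldChange(doubled)$fc * foldChange(swapped)$fc, 1)
  # scale invariance: multiplying every area by a constant preserves FCs
  scaled <- doubled; scaled$area <- scaled$area * 37.5
  expect_equal(foldChange(scaled)$fc, foldChange(doubled)$fc,
               tolerance = 1e-12)
})

test_that("protection calls are gated on LiP status, FC and significance", {
  lip <- data.frame(peptide_id = c("a", "b"),
                    mean_ratio_dd_vs_tryp = c(0.2, 1.0),
                    p_value = c(0.001, 0.8), is_lip = c(TRUE, FALSE))
  fcs <- data.frame(peptide_id = c("a", "a", "b"), dose_uM = c(1, 10, 1),
                    fc = c(1.0, 2.0, 3.0), p_value = c(0.9, 0.01, 0.001))
  expect_equal(callProtected(lip, fcs), "a")
  # a non-LiP peptide is never called, whatever its fold change
  expect_false("b" %in% callProtected(lip, fcs))
  # fc = 1 everywhere: nothing called
  flat <- fcs; flat$fc <- 1
  expect_length(callProtected(lip, flat), 0L)
  # monotone in fc_min and alpha
  expect_length(callProtected(lip, fcs, fcMin = 2.5), 0L)
  expect_length(callProtected(lip, fcs, alpha = 0.001), 0L)
  expect_length(callProtected(lip, fcs, fcMin = 1.1, alpha = 0.05), 1L)
})

test_that("region mapping merges peptides and intersects annotations", {
  ann <- data.frame(
    name = c("helix_2", "gate_loop", "Tyr75"),
    start = c(49L, 279L, 75L), end = c(77L, 289L, 75L),
    kind = c("helix", "loop", "residue"))
  prot <- ProteinRecord("pygb_like",
                        paste(rep("A", 400), collapse = ""), ann)
  rep1 <- mapRegions(prot, data.frame(start = 71, end = 78))
  ov <- regionOverlaps(rep1)
  expect_equal(ov$overlap_length[ov$name == "helix_2"], 7L)
  expect_true("Tyr75" %in% ov$name)   # key residue inside the interval
  rep2 <- mapRegions(prot, data.frame(start = 279, end = 290))
  expect_equal(regionOverlaps(rep2)$overlap_length[
    regionOverlaps(rep2)$name == "gate_loop"], 11L)
  # bookended peptides merge into one interval
  rep3 <- mapRegions(prot, data.frame(start = c(10, 21), end = c(20, 30)))
  expect_equal(protectedIntervals(rep3),
               data.frame(start = 10L, end = 30L))
  expect_error(mapRegions(prot, data.frame(start = 100, end = 500)),
               "outside")
  expect_output(show(rep1), "1 protected interval")
})

test_that("merged intervals conserve the covered residue set", {
  prot <- ProteinRecord("p", paste(rep("A", 300), collapse = ""))
  set.seed(14)
  for (i in 1:10) {
    st <- sample(1:280, 8); en <- pmin(st + sample(5:30, 8, TRUE), 300)
    rep <- mapRegions(prot, data.frame(start = st, end = en))
    iv <- protectedIntervals(rep)
    covered <- unique(unlist(mapply(seq, st, en)))
    merged <- unlist(mapply(seq, iv$start, iv$end))
    expect_setequal(merged, covered)
    expect_false(is.unsorted(iv$start))
    if (nrow(iv) > 1) expect_true(all(iv$start[-1] > iv$end[-nrow(iv)] + 1))
  }
})

test_that("the t-LiP summary mirrors the targeted-MRM report layout", {
  sim <- simulateTlipAreas(3, noiseCv = 0.05)
  lip <- selectLipPeptides(sim$areas)
  fcs <- foldChange(sim$areas)
  prot <- callProtected(lip, fcs)
  summ <- tlipSummary(sim$peptides, lip, fcs, prot)
  expect_true(all(c("sequence", "precursor_mz_2plus", "daughter_mz",
                    "length", "fc_1uM", "p_fc_1uM", "p_lip",
                    "protected") %in% names(summ)))
  expect_equal(nrow(summ), nrow(sim$peptides))
  expect_equal(summ$length, nchar(summ$sequence))
  expect_true(all(summ$precursor_mz_2plus > 0))
})
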