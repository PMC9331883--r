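test_that("ProteinRecord validates its sequence and annotations", {
  p <- ProteinRecord("p1", "magkpeptidek")
  expect_equal(proteinSequence(p), "MAGKPEPTIDEK")
  expect_equal(proteinLength(p), 12L)
  expect_error(ProteinRecord("p1", "MAXGK"), "position 3")
  expect_error(ProteinRecord("p1", "MAGUK"), "position 4")
  expect_error(ProteinRecord("p1", ""), "non-empty")
  expect_error(
    ProteinRecord("p1", "MAGK", data.frame(name = "d", start = 2, end = 9,
                                           kind = "domain")),
    "start <= end <= protein length")
  expect_error(
    ProteinRecord("p1", "MAGK", data.frame(name = "d", start = 1, end = 2,
                                           kind = "turn")),
    "kind")
  expect_output(show(p), "ProteinRecord 'p1': 12 residues")
})

test_that("digestTryptic handles cleavage, missed cleavages and the proline rule", {
  # no cleavage sites at all
  one <- digestTryptic("MAAA", 0)
  expect_equal(nrow(one), 1L)
  expect_equal(one$sequence, "MAAA")
  expect_equal(c(one$start, one$end), c(1L, 4L))

  # R followed by P is not a cleavage site
  akrpc <- digestTryptic("AKRPC", 1)
  expect_equal(akrpc$sequence, c("AK", "AKRPC", "RPC"))
  expect_equal(akrpc$n_missed, c(0L, 1L, 0L))

  # exhaustive: KKK with 2 missed cleavages gives all 6 intervals
  kkk <- digestTryptic("KKK", 2)
  expect_equal(nrow(kkk), 6L)
  expect_equal(kkk[, c("start", "end")],
               data.frame(start = c(1L, 1L, 1L, 2L, 2L, 3L),
                          end = c(1L, 2L, 3L, 2L, 3L, 3L)))
  expect_error(digestTryptic("MABK", 0), "position 3")
})

test_that("digestion matches the exhaustive brute-force oracle", {
  set.seed(11)
  for (i in 1:60) {
    seqStr <- paste(sample(AA_LETTERS, sample(1:12, 1), replace = TRUE),
                    collapse = "")
    for (mm in 0:2) {
      got <- digestTryptic(seqStr, mm)[, c("start", "end")]
      want <- oracleDigest(seqStr, mm)
      rownames(got) <- rownames(want) <- NULL
      expect_equal(got, want, info = sprintf("%s mm=%d", seqStr, mm))
    }
    got <- enumerateSemitryptic(seqStr, 1, nchar(seqStr))[, c("start", "end")]
    want <- oracleSemi(seqStr, 1, nchar(seqStr))
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got, want, info = seqStr)
  }
})

test_that("zero-missed tryptic peptides tile the protein exactly", {
  set.seed(4)
  for (i in 1:10) {
    seqStr <- paste(sample(AA_LETTERS, 80, replace = TRUE), collapse = "")
    peps <- digestTryptic(seqStr, 0)
    expect_equal(paste(peps$sequence, collapse = ""), seqStr)
    expect_equal(peps$start[-1], peps$end[-nrow(peps)] + 1L)
  }
})

test_that("semi-tryptic enumeration excludes fully tryptic peptides", {
  # protein termini are tryptic, so "KA" yields no semi-tryptic peptide
  expect_equal(nrow(enumerateSemitryptic("KA", 1, 2)), 0L)
  semi <- enumerateSemitryptic("MKGGGR", 2, 3)
  expect_true(all(semi$terminal_status == "semi_tryptic"))
  expect_true(any(semi$start == 3 & semi$end == 4))   # "GG"
  # disjoint from the fully tryptic listing
  seqStr <- "MAGKPEPTIDEKAR"
  full <- digestTryptic(seqStr, nchar(seqStr))
  semi <- enumerateSemitryptic(seqStr, 1, nchar(seqStr))
  expect_length(intersect(paste(full$start, full$end),
                          paste(semi$start, semi$end)), 0L)
  # minLen beyond protein length: empty, not an error
  expect_equal(nrow(enumerateSemitryptic("MAGK", 10, 20)), 0L)
  expect_error(enumerateSemitryptic("MAGK", 3, 2), "minLen")
})

test_that("peptide masses match reference values and are additive", {
  expect_equal(peptideMass("G", mods = character()), 75.03203,
               tolerance = 1e-7)
  expect_equal(peptideMass("PEPTIDE", mods = character()), 799.35997,
               tolerance = 1e-6)
  # fixed carbamidomethyl adds exactly its delta on C
  expect_equal(peptideMass("C"), peptideMass("C", mods = character()) +
                 57.02146, tolerance = 1e-9)
  # oxidation adds its delta per M
  expect_equal(peptideMass("MM", mods = "oxidation"),
               peptideMass("MM", mods = character()) + 2 * 15.99491,
               tolerance = 1e-9)
  expect_error(peptideMass("PEPTIDE", mods = "acetyl"),
               "supported modifications")
  # additivity: mass(AB) = mass(A) + mass(B) - water
  set.seed(21)
  for (i in 1:20) {
    pep <- randomPeptide(4, 16)
    k <- sample(2:(nchar(pep) - 1), 1)
    a <- substr(pep, 1, k); b <- substr(pep, k + 1, nchar(pep))
    expect_equal(peptideMass(pep, mods = character()),
                 peptideMass(a, mods = character()) +
                   peptideMass(b, mods = character()) - 18.010565,
                 tolerance = 1e-9)
  }
  # average masses are heavier than monoisotopic for any real peptide
  expect_gt(peptideMass("PEPTIDE", mods = character(), kind = "average"),
            peptideMass("PEPTIDE", mods = character()))
})

test_that("precursorMz applies standard m/z arithmetic", {
  expect_equal(precursorMz(1000, 1), 1001.007276)
  expect_equal(precursorMz(1000, 2), 501.007276)
  expect_equal(precursorMz(peptideMass("PEPTIDE", mods = character()), 2),
               400.68726, tolerance = 1e-6)
  expect_error(precursorMz(1000, 0), "positive")
  expect_error(precursorMz(1000, -2), "positive")
})

test_that("fragment ions satisfy the b/y complementarity identity", {
  f <- fragmentIons("AG", mods = character())
  expect_equal(f$mz[f$series == "b" & f$index == 1], 72.04439,
               tolerance = 1e-6)
  expect_equal(f$mz[f$series == "y" & f$index == 1], 76.03930,
               tolerance = 1e-6)
  expect_error(fragmentIons("A"), "at least 2")
  set.seed(31)
  for (i in 1:50) {
    pep <- randomPeptide(2, 25)
    n <- nchar(pep)
    f <- fragmentIons(pep, mods = character())
    m <- peptideMass(pep, mods = character())
    b <- f$mz[f$series == "b"][order(f$index[f$series == "b"])]
    y <- f$mz[f$series == "y"][order(f$index[f$series == "y"])]
    expect_equal(b + rev(y), rep(m + 2 * 1.007276, n - 1),
                 tolerance = 1e-9)
  }
  # modifications travel with the fragment containing the residue
  fm <- fragmentIons("CAG")
  f0 <- fragmentIons("CAG", mods = character())
  expect_equal(fm$mz[fm$series == "b"] - f0$mz[f0$series == "b"],
               rep(57.02146, 2), tolerance = 1e-9)
  expect_equal(fm$mz[fm$series == "y" & fm$index == 1],
               f0$mz[f0$series == "y" & f0$index == 1])
})

test_that("selectTransitions filters digestTryptic output deterministically", {
  prot <- makeProtein(3, length = 200)
  tr <- selectTransitions(prot)
  # consistency: every candidate peptide is a 0-missed tryptic peptide
  # within length bounds
  peps <- digestTryptic(prot, 0)
  len <- peps$end - peps$start + 1
  keep <- peps[len >= 6 & len <= 25, ]
  expect_setequal(unique(tr$peptide), keep$sequence)
  # y-ions only, above the low-mass cutoff, top-3 by index descending
  expect_true(all(tr$fragment_series == "y"))
  expect_true(all(tr$fragment_mz >= 300))
  expect_true(all(table(paste(tr$peptide, tr$precursor_z)) <= 3))
  expect_true(all(tr$precursor_z %in% c(2L, 3L)))
  # deterministic under re-running
  expect_identical(tr, selectTransitions(prot))
  # K larger than available y-ions: clamped, no error
  small <- ProteinRecord("s", "MAGPEPK")
  trBig <- selectTransitions(small, nFragments = 50, mzCutoff = 0)
  expect_equal(nrow(trBig[trBig$precursor_z == 2, ]), 6L)  # len 7 -> 6 y ions
  # short protein: warning and empty result
  expect_warning(out <- selectTransitions(ProteinRecord("t", "MAG")),
                 "shorter")
  expect_equal(nrow(out), 0L)
  # exclusion set removes peptides containing the residue
  trNoC <- selectTransitions(prot, excludeResidues = "C")
  expect_false(any(grepl("C", trNoC$peptide)))
})

test_that("mapPeptide reports all (even overlapping) occurrences 1-based", {
  expect_equal(mapPeptide("GAGA", "GA"),
               data.frame(start = c(1L, 3L), end = c(2L, 4L)))
  prot <- makeProtein(9, length = 120)
  expect_equal(mapPeptide(prot, proteinSequence(prot)),
               data.frame(start = 1L, end = 120L))
  # overlapping occurrences are found
  expect_equal(mapPeptide("AAAA", "AAA"),
               data.frame(start = c(1L, 2L), end = c(3L, 4L)))
  expect_equal(nrow(mapPeptide("GAGA", "W")), 0L)
  # a random window maps back to its position
  set.seed(5)
  s <- proteinSequence(prot)
  for (i in 1:10) {
    st <- sample(1:(120 - 5), 1)
    hit <- mapPeptide(prot, substr(s, st, st + 5))
    expect_true(any(hit$start == st & hit$end == st + 5))
  }
  expect_error(mapPeptide("GAGA", ""), "non-empty")
})
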