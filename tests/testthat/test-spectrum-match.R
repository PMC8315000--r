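byCfg <- fragmentConfig(series = c("b", "y"), losses = "none",
                        maxCharge = 1L)
ppm20 <- tolerance(20, "ppm")

test_that("noiseless self-spectra annotate completely; empty spectra do not", {
  sp <- cleanSpectrum("KLVVGAVGV", byCfg)
  ann <- annotateSpectrum(sp, "KLVVGAVGV", ppm20, fragCfg = byCfg)
  expect_equal(ann$matchedIonCount, ann$nTheoretical)
  expect_equal(nrow(ann$unmatchedIons), 0L)
  expect_equal(ann$matchedIntensityFraction, 1)

  empty <- Spectrum()
  ann0 <- annotateSpectrum(empty, "KLVVGAVGV", ppm20, fragCfg = byCfg)
  expect_equal(ann0$matchedIonCount, 0L)
})

test_that("10 ppm jitter is recovered at 20 ppm tolerance for ~95% of ions", {
  cfg <- byCfg
  s <- paste(rep("KLVVGAVGVTESIHR", 1), collapse = "")
  total <- 0L; matched <- 0L
  set.seed(100)
  for (seed in 1:500) {
    sp <- cleanSpectrum(s, cfg, jitterPpm = 10)
    ann <- annotateSpectrum(sp, s, ppm20, fragCfg = cfg)
    total <- total + ann$nTheoretical
    matched <- matched + ann$matchedIonCount
  }
  expect_gte(matched / total, 0.95)   # P(|N(0,10)| <= 20) ~ 0.9545
})

test_that("annotation is deterministic and monotone in the tolerance", {
  set.seed(12)
  sp <- cleanSpectrum("KLVVGAVGVTES", byCfg, jitterPpm = 15)
  a1 <- annotateSpectrum(sp, "KLVVGAVGVTES", ppm20, fragCfg = byCfg)
  a2 <- annotateSpectrum(sp, "KLVVGAVGVTES", ppm20, fragCfg = byCfg)
  expect_identical(a1$matches, a2$matches)
  counts <- vapply(c(1, 5, 10, 20, 50), function(v)
    annotateSpectrum(sp, "KLVVGAVGVTES", tolerance(v, "ppm"),
                     fragCfg = byCfg)$matchedIonCount, integer(1))
  expect_true(all(diff(counts) >= 0))
})

test_that("agreement between two spectra mirrors the red/blue comparison", {
  sp <- cleanSpectrum("KLVVGAVGV", byCfg)
  agIdent <- spectraAgreement(sp, sp, "KLVVGAVGV", ppm20, fragCfg = byCfg)
  expect_length(agIdent$uniqueTo1, 0L)
  expect_length(agIdent$uniqueTo2, 0L)

  other <- Spectrum(c(1500, 1600), c(10, 10))
  agDisj <- spectraAgreement(sp, other, "KLVVGAVGV", ppm20, fragCfg = byCfg)
  expect_length(agDisj$shared, 0L)
  expect_setequal(agDisj$uniqueTo1,
                  theoreticalFragments("KLVVGAVGV", cfg = byCfg)$label)

  # independent per-ion detection 0.8 -> shared fraction ~ 0.64
  m <- nrow(theoreticalFragments("KLVVGAVGVTESIHR", cfg = byCfg))
  shared <- 0L
  set.seed(200)
  for (seed in 1:500) {
    s1 <- simulateMs2("KLVVGAVGVTESIHR", seed = 2 * seed,
                      simCfg = spectrumSimConfig(p = 0.8, jitterPpm = 0,
                                                 nNoise = 0),
                      fragCfg = byCfg)
    s2 <- simulateMs2("KLVVGAVGVTESIHR", seed = 2 * seed + 1,
                      simCfg = spectrumSimConfig(p = 0.8, jitterPpm = 0,
                                                 nNoise = 0),
                      fragCfg = byCfg)
    shared <- shared +
      length(spectraAgreement(s1, s2, "KLVVGAVGVTESIHR", ppm20,
                              fragCfg = byCfg)$shared)
  }
  fracHat <- shared / (500 * m)
  sdHat <- sqrt(0.64 * 0.36 / (500 * m))
  expect_lt(abs(fracHat - 0.64), 3 * sdHat)
})

test_that("diagnostic partition of the isobaric KRAS pair matches the composition oracle", {
  rep <- diagnosticIons("KLVVGAVGV", "KLVVVGAVG", tolerance(0.02, "Da"),
                        fragCfg = byCfg)
  expect_setequal(rep$diagnosticA$label,
                  c("b5", "b6", "b8", "y1", "y3", "y4"))
  expect_setequal(rep$sharedA$label,
                  c("b1", "b2", "b3", "b4", "b7",
                    "y2", "y5", "y6", "y7", "y8"))
  # symmetric, equal-size diagnostics for isomers
  expect_setequal(rep$diagnosticB$label, rep$diagnosticA$label)

  # oracle: equal residue composition <=> mass-shared, per prefix/suffix
  ca <- fragmentCompositions("KLVVGAVGV")
  cb <- fragmentCompositions("KLVVVGAVG")
  for (i in 1:8) {
    expect_equal(sprintf("b%d", i) %in% rep$sharedA$label,
                 ca$prefix[i] %in% cb$prefix)
    expect_equal(sprintf("y%d", i) %in% rep$sharedA$label,
                 ca$suffix[i] %in% cb$suffix)
  }

  ident <- diagnosticIons("KLVVGAVGV", "KLVVGAVGV",
                          tolerance(0.02, "Da"), fragCfg = byCfg)
  expect_equal(nrow(ident$diagnosticA), 0L)
  expect_equal(nrow(ident$sharedA), 16L)

  disjoint <- diagnosticIons("GK", "WW", tolerance(0.02, "Da"),
                             fragCfg = byCfg)
  expect_equal(nrow(disjoint$sharedA), 0L)
  expect_equal(nrow(disjoint$sharedB), 0L)
})

test_that("diagnostic support in a spectrum drives the verdict", {
  tolDa <- tolerance(0.02, "Da")
  rep0 <- diagnosticIons("KLVVGAVGV", "KLVVVGAVG", tolDa, fragCfg = byCfg)

  spA <- cleanSpectrum("KLVVGAVGV", byCfg)
  repA <- supportInSpectrum(spA, rep0, tolDa)
  expect_equal(repA$supportA, nrow(rep0$diagnosticA))
  expect_equal(repA$supportB, 0L)
  expect_equal(repA$verdict, "A")

  sharedOnly <- Spectrum(rep0$sharedA$mz, rep(50, nrow(rep0$sharedA)))
  repS <- supportInSpectrum(sharedOnly, rep0, tolDa)
  expect_equal(repS$verdict, "ambiguous")

  # simulated A spectra at detection 0.8 pick A in nearly every seed
  verdicts <- vapply(1:200, function(seed) {
    sp <- simulateMs2("KLVVGAVGV", seed = seed,
                      simCfg = spectrumSimConfig(p = 0.8, jitterPpm = 2,
                                                 nNoise = 0),
                      fragCfg = byCfg)
    supportInSpectrum(sp, rep0, tolDa)$verdict
  }, character(1))
  expect_gte(mean(verdicts == "A"), 0.99)
})

test_that("surrogate match score behaves like an ion score", {
  expect_equal(matchScore(Spectrum(), "KLVVGAVGV", ppm20,
                          fragCfg = byCfg), 0)
  # no matching ions -> score 0
  off <- Spectrum(c(1500, 1600, 1700), c(1, 1, 1))
  expect_equal(matchScore(off, "KLVVGAVGV", ppm20, fragCfg = byCfg), 0)

  # true peptide outscores an equal-composition shuffled decoy
  set.seed(77)
  wins <- 0L
  for (seed in 1:200) {
    s <- randomPeptide(10)
    decoy <- s
    while (decoy == s)
      decoy <- paste(sample(strsplit(s, "")[[1]]), collapse = "")
    sp <- simulateMs2(s, seed = seed,
                      simCfg = spectrumSimConfig(p = 0.9, jitterPpm = 3,
                                                 nNoise = 10),
                      fragCfg = byCfg)
    if (matchScore(sp, s, ppm20, fragCfg = byCfg) >
        matchScore(sp, decoy, ppm20, fragCfg = byCfg))
      wins <- wins + 1L
  }
  expect_gte(wins / 200, 0.95)

  # adding a peak at an unmatched theoretical ion never lowers the score
  fr <- theoreticalFragments("KLVVGAVGV", cfg = byCfg)
  partial <- Spectrum(fr$mz[1:4], rep(10, 4))
  fuller <- Spectrum(fr$mz[1:5], rep(10, 5))
  expect_gte(matchScore(fuller, "KLVVGAVGV", ppm20, fragCfg = byCfg),
             matchScore(partial, "KLVVGAVGV", ppm20, fragCfg = byCfg))
})

test_that("RT resolution uses a strict boundary", {
  expect_false(rtResolved(10.0, 10.0, 0.5))
  expect_true(rtResolved(10.0, 12.0, 0.5))
  expect_false(rtResolved(10.0, 10.5, 0.5))
})
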