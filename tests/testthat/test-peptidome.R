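test_that("non-spliced enumeration lists exactly the bounded substrings", {
  acde <- Substrate("ACDE")
  cfg3 <- enumerationConfig(3, 3)
  db <- enumerateNonspliced(acde, cfg3)
  expect_setequal(db$sequence, c("ACD", "CDE"))
  expect_equal(db$origins[db$sequence == "ACD"], "1-3")
  expect_equal(db$origins[db$sequence == "CDE"], "2-4")

  kras <- krasSubstrate()
  db9 <- enumerateNonspliced(kras, enumerationConfig(9, 9))
  expect_true("KLVVVGAVG" %in% db9$sequence)
  expect_equal(db9$origins[db9$sequence == "KLVVVGAVG"], "5-13")

  # min length above the substrate length
  empty <- enumerateNonspliced(acde, enumerationConfig(5, 6))
  expect_equal(nrow(empty), 0L)
})

test_that("cis-spliced enumeration matches the hand-derived small cases", {
  acde <- Substrate("ACDE")
  normalOnly <- enumerationConfig(3, 3, allowReverse = FALSE)
  db <- enumerateCisSpliced(acde, normalOnly)
  expect_setequal(db$sequence, c("ADE", "ACE"))
  expect_equal(db$origins[db$sequence == "ADE"], "1-1/3-4")
  expect_equal(db$origins[db$sequence == "ACE"], "1-2/4-4")

  ev <- enumerateCisSpliced(acde, enumerationConfig(3, 3), collapse = FALSE)
  revSeqs <- unique(ev$sequence[ev$kind == "cis_reverse"])
  expect_setequal(revSeqs, c("DAC", "EAC", "ECD", "DEA", "DEC", "CDA"))

  kras <- krasSubstrate()
  db9 <- enumerateCisSpliced(kras, enumerationConfig(9, 9))
  row <- db9[db9$sequence == "KLVVGAVGV", ]
  expect_equal(nrow(row), 1L)
  expect_true("5-6/8-14" %in% strsplit(row$origins, ";")[[1]])
})

test_that("optimized cis enumeration agrees with the brute-force double loop", {
  set.seed(42)
  for (rep in 1:40) {
    n <- sample(4:12, 1)
    s <- randomPeptide(n, alphabet = c("A", "C", "D", "E"))
    sub <- Substrate(s)
    minL <- sample(2:4, 1)
    maxL <- sample(minL:(n + 2), 1)
    allowRev <- rep %% 2 == 0
    cfg <- enumerationConfig(minL, maxL, allowReverse = allowRev)
    ev <- enumerateCisSpliced(sub, cfg, collapse = FALSE)
    oracle <- bruteCisEvents(s, 1L, minL, maxL, allowReverse = allowRev)
    expect_setequal(paste(ev$sequence, ev$kind, ev$origin),
                    paste(oracle$sequence, oracle$kind, oracle$origin))
    expect_setequal(unique(ev$sequence), unique(oracle$sequence))
  }
})

test_that("every returned origin reconstructs its product sequence", {
  set.seed(7)
  for (rep in 1:10) {
    s <- randomPeptide(sample(6:12, 1), alphabet = c("G", "A", "V", "K"))
    offset <- sample(1:5, 1)
    sub <- Substrate(s, offset = offset)
    cfg <- enumerationConfig(3, 8)
    ev <- rbind(enumerateNonspliced(sub, cfg, collapse = FALSE),
                enumerateCisSpliced(sub, cfg, collapse = FALSE))
    for (k in seq_len(nrow(ev))) {
      o <- parseOrigin(ev$origin[k])
      rebuilt <- if (o$kind == "nonspliced")
        substr(s, o$start - offset + 1, o$end - offset + 1)
      else paste0(substr(s, o$r1_start - offset + 1, o$r1_end - offset + 1),
                  substr(s, o$r2_start - offset + 1, o$r2_end - offset + 1))
      expect_identical(rebuilt, ev$sequence[k])
    }
  }
})

test_that("non-spliced event count follows N - L + 1", {
  set.seed(11)
  for (rep in 1:10) {
    n <- sample(5:12, 1)
    s <- randomPeptide(n, alphabet = c("A", "C", "D", "E"))
    L <- sample(2:(n + 1), 1)
    ev <- enumerateNonspliced(Substrate(s), enumerationConfig(L, L),
                              collapse = FALSE)
    expect_equal(nrow(ev), max(0, n - L + 1))
  }
})

test_that("sequence classification separates spliced-only from substrings", {
  kras <- krasSubstrate()
  expect_equal(classifySequence("KLVVGAVGV", kras), "spliced_only")
  expect_equal(classifySequence("KLVVVGAVG", kras), "nonspliced")
  expect_equal(classifySequence("WWWW", kras), "not_producible")
  expect_error(classifySequence("KLX", kras), "non-canonical")

  # nonspliced classification implies enumeration membership
  set.seed(3)
  for (rep in 1:10) {
    s <- randomPeptide(10, alphabet = c("A", "C", "D", "E"))
    sub <- Substrate(s)
    cfg <- enumerationConfig(3, 10)
    db <- enumerateNonspliced(sub, cfg)
    pep <- substr(s, 3, 7)
    expect_equal(classifySequence(pep, sub, cfg), "nonspliced")
    expect_true(pep %in% db$sequence)
  }

  # reverse-only products stop being producible when reverse is disabled
  sub <- Substrate("ACDE")
  expect_equal(classifySequence("EAC", sub), "spliced_only")
  expect_equal(classifySequence("EAC", sub,
                                enumerationConfig(allowReverse = FALSE)),
               "not_producible")
})

test_that("origin notation round-trips and rejects malformed text", {
  expect_equal(parseOrigin("5-13")$kind, "nonspliced")
  o <- parseOrigin("5-6/8-14")
  expect_equal(o$kind, "cis_normal")
  expect_equal(unlist(o[-1]), c(r1_start = 5, r1_end = 6,
                                r2_start = 8, r2_end = 14))
  expect_equal(parseOrigin("7-9/2-4")$kind, "cis_reverse")
  for (txt in c("5-13", "5-6/8-14", "7-9/2-4"))
    expect_identical(formatOrigin(parseOrigin(txt)), txt)
  expect_error(parseOrigin("5-6/7-9"), "not a valid splice")
  expect_error(parseOrigin("9-5"), "start > end")
  expect_error(parseOrigin("abc"), "malformed")
})

test_that("peptidoform expansion enumerates modification subsets", {
  expect_length(expandModifications("KLVVGAVGV"), 1L)
  expect_length(expandModifications("NQM", maxVariableMods = 3), 8L)
  forms1 <- expandModifications("NQM", maxVariableMods = 1)
  expect_length(forms1, 4L)
  sizes <- vapply(forms1, function(f) nrow(f$mods), integer(1))
  expect_setequal(sizes, c(0L, 1L))
  deltas <- unlist(lapply(forms1, function(f) f$mods$delta))
  expect_setequal(round(deltas, 6), c(0.984016, 15.994915))
})
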