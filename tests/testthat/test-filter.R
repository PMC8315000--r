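hitRow <- function(scan, rank, seq, cat, score, q = 0.01) {
  data.frame(scan_id = scan, rank = rank, sequence = seq, category = cat,
             ion_score = score, q_value = q)
}

test_that("the worked filter cases decide as the rule prescribes", {
  cfg <- filterConfig()

  # spliced candidate at rank 2 is never accepted
  h1 <- rbind(hitRow("s1", 1, "KLVVVGAVG", "nonspliced", 45),
              hitRow("s1", 2, "KLVVGAVGV", "spliced", 40))
  r1 <- filterHits(h1, cfg)
  expect_equal(r1$scans$accepted_sequence, "KLVVVGAVG")
  expect_equal(r1$hits$reason[r1$hits$rank == 2], "not_rank1")

  # delta to the best non-spliced hit of 25% < 30% rejects
  h2 <- rbind(hitRow("s2", 1, "KLVVGAVGV", "spliced", 40),
              hitRow("s2", 2, "KLVVVGAVG", "nonspliced", 30))
  r2 <- filterHits(h2, cfg)
  expect_true(is.na(r2$scans$accepted_sequence))
  expect_equal(r2$scans$reason, "delta_sn_fail")

  # 50 / 40 / 30 passes both delta conditions
  h3 <- rbind(hitRow("s3", 1, "KLVVGAVGV", "spliced", 50),
              hitRow("s3", 2, "KLVVGAVVG", "spliced", 40),
              hitRow("s3", 3, "KLVVVGAVG", "nonspliced", 30))
  r3 <- filterHits(h3, cfg)
  expect_equal(r3$scans$accepted_sequence, "KLVVGAVGV")

  # 19.9 sits below the inclusive >= 20 cutoff
  h4 <- hitRow("s4", 1, "KLVVVGAVG", "nonspliced", 19.9)
  expect_equal(filterHits(h4, cfg)$scans$reason, "below_score")
  expect_equal(filterHits(hitRow("s5", 1, "KLVVVGAVG", "nonspliced",
                                 20))$scans$accepted_sequence, "KLVVVGAVG")
})

test_that("tie, q-value, delta-ss and negative-score branches reject", {
  tie <- rbind(hitRow("t", 1, "KLVVGAVGV", "spliced", 40),
               hitRow("t", 1, "KLVVVGAVG", "nonspliced", 40))
  expect_equal(filterHits(tie)$scans$reason, "ambiguous_tie")

  badQ <- hitRow("q", 1, "KLVVVGAVG", "nonspliced", 40, q = 0.2)
  expect_equal(filterHits(badQ)$scans$reason, "above_q")

  ss <- rbind(hitRow("ss", 1, "KLVVGAVGV", "spliced", 50),
              hitRow("ss", 2, "KLVVGAVVG", "spliced", 48))
  expect_equal(filterHits(ss)$scans$reason, "delta_ss_fail")

  neg <- rbind(hitRow("n", 1, "KLVVGAVGV", "spliced", -5),
               hitRow("n", 2, "KLVVVGAVG", "nonspliced", -10))
  expect_equal(filterHits(neg)$scans$reason, "below_score")

  # OR combination accepts when only one delta condition holds
  h <- rbind(hitRow("o", 1, "KLVVGAVGV", "spliced", 50),
             hitRow("o", 2, "KLVVGAVVG", "spliced", 40),   # dss = 20 >= 10
             hitRow("o", 3, "KLVVVGAVG", "nonspliced", 40)) # dsn = 20 < 30
  expect_true(is.na(filterHits(h)$scans$accepted_sequence))
  expect_equal(filterHits(h, filterConfig(deltaCombine = "or")
                          )$scans$accepted_sequence, "KLVVGAVGV")
})

test_that("filtering is idempotent and anti-monotone in strictness", {
  sim <- simulateHitTable(400, seed = 31)
  res <- filterHits(sim$hits)
  accepted <- res$scans[!is.na(res$scans$accepted_sequence), ]

  # idempotence: refiltering only the accepted top hits accepts them all
  keep <- res$hits[res$hits$accepted, , drop = FALSE]
  keep <- keep[, c("scan_id", "rank", "sequence", "category", "ion_score",
                   "q_value")]
  again <- filterHits(keep)
  expect_equal(sum(!is.na(again$scans$accepted_sequence)), nrow(accepted))

  # stricter thresholds never accept more scans
  nAccept <- function(cfg) sum(!is.na(filterHits(sim$hits,
                                                 cfg)$scans$accepted_sequence))
  base <- nAccept(filterConfig())
  expect_lte(nAccept(filterConfig(scoreMin = 30)), base)
  expect_lte(nAccept(filterConfig(deltaSplicedSpliced = 20)), base)
  expect_lte(nAccept(filterConfig(deltaSplicedNonspliced = 50)), base)
  expect_lte(nAccept(filterConfig(qMax = 0.01)), base)

  # the accepted hit always carries the scan's maximal score
  byScan <- split(res$hits, res$hits$scan_id)
  for (h in byScan)
    if (any(h$accepted))
      expect_equal(h$ion_score[h$accepted], max(h$ion_score))
})

test_that("decisions agree with the generator's closed-form ground truth", {
  sim <- simulateHitTable(2000, seed = 17)
  res <- filterHits(sim$hits)
  merged <- merge(res$scans, sim$truth, by = "scan_id")
  expect_equal(nrow(merged), 2000L)
  expect_identical(!is.na(merged$accepted_sequence), merged$expect_accept)
  expect_identical(merged$accepted_sequence, merged$expect_sequence)
  expect_identical(merged$reason, merged$expect_reason)
})

test_that("hit tables round-trip through CSV and derive categories", {
  hits <- rbind(hitRow("a", 1, "KLVVGAVGV", "spliced", 50),
                hitRow("a", 2, "KLVVVGAVG", "nonspliced", 20),
                hitRow("b", 1, "TEYKL", "nonspliced", 33))
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(hits, path, row.names = FALSE)
  back <- readHitTable(path)
  expect_equal(back[, names(hits)], hits)

  # no category column: classified against the substrate
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(hits[, setdiff(names(hits), "category")], path2,
            row.names = FALSE)
  filled <- readHitTable(path2, substrate = krasSubstrate())
  expect_equal(filled$category[filled$sequence == "KLVVGAVGV"], "spliced")
  expect_equal(filled$category[filled$sequence == "KLVVVGAVG"],
               "nonspliced")

  # report writing and empty input
  rpt <- withr::local_tempfile(fileext = ".csv")
  writeFilterReport(filterHits(hits), rpt)
  expect_equal(nrow(read.csv(rpt)), 2L)
  expect_equal(nrow(filterHits(hits[0, ])$scans), 0L)
  expect_error(readHitTable(path2), "no substrate")
})

test_that("target-decoy q-values are monotone and correctly counted", {
  score <- c(50, 45, 40, 35, 30, 25)
  decoy <- c(FALSE, FALSE, TRUE, FALSE, TRUE, FALSE)
  q <- targetDecoyQValues(score, decoy)
  # at score 40: 1 decoy / 2 targets = 0.5; improved by lower thresholds
  expect_equal(q[1], 0)
  expect_true(all(diff(q[order(-score)]) >= 0))
  expect_equal(q[4], 1 / 3)
})
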