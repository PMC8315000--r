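win <- mzWindow(421.275, 421.875)

twoPeptideRun <- function(seed = 1, amounts = c(A = 100, B = 80),
                          rtA = 10, rtB = 12, noise = 0.01) {
  cfg <- chromSimConfig(
    data.frame(label = c("A", "B"), mz = c(421.4, 421.6),
               ref_rt = c(rtA, rtB), sigma = 0.1),
    noiseLevel = noise)
  simulateRun(amounts, seed = seed, chromCfg = cfg)
}

test_that("XIC extraction sums in-window intensity per scan", {
  run <- twoPeptideRun(noise = 0)
  # nothing in a far-away window
  blank <- extractXic(run, mzWindow(500, 501))
  expect_true(all(blank$intensity == 0))
  expect_equal(nrow(blank), length(scanTimes(run)))

  trace <- extractXic(run, win)
  expect_equal(trace$rt[which.max(trace$intensity)], 10, tolerance = 0.15)

  # two co-windowed peptides give two local maxima ~2 min apart
  apexA <- trace$rt[which.max(trace$intensity)]
  narrowB <- extractXic(run, mzWindow(421.55, 421.65))
  apexB <- narrowB$rt[which.max(narrowB$intensity)]
  expect_equal(apexB - apexA, 2, tolerance = 0.2)

  # window monotonicity: a larger window never loses intensity
  wide <- extractXic(run, mzWindow(421.0, 422.0))
  expect_true(all(wide$intensity >= trace$intensity - 1e-12))
})

test_that("peak detection calls presence by RT match and SNR", {
  flat <- structure(data.frame(rt = seq(5, 15, 0.02), intensity = 0),
                    class = c("XicTrace", "data.frame"))
  expect_false(detectPeak(flat, 10, 0.5, 3)$present)

  tr <- gaussianTrace(100, apexRt = 10, noise = 0.05)
  set.seed(1)
  call <- detectPeak(tr, 10, 0.5, 3)
  expect_true(call$present)
  expect_lte(abs(call$apexRt - 10), 0.02)
  expect_gt(call$snr, 50)

  # a peak 3x rtTol away from the reference is not picked up
  callFar <- detectPeak(gaussianTrace(100, apexRt = 11.5), 10, 0.5, 3)
  expect_false(callFar$present)
  expect_equal(callFar$area, 0)
})

test_that("trapezoidal integration recovers analytic Gaussian areas", {
  tr0 <- gaussianTrace(0, 10)
  expect_equal(integrateArea(tr0, detectPeak(tr0, 10, 0.5, 3)), 0)

  set.seed(21)
  for (rep in 1:100) {
    A <- runif(1, 50, 500)
    tr <- gaussianTrace(A, apexRt = runif(1, 8, 12), sigma = 0.1,
                        noise = A / 5000)
    call <- detectPeak(tr, tr$rt[which.max(tr$intensity)], 0.5, 10)
    expect_true(call$present)
    expect_gte(call$snr, 10)
    area <- integrateArea(tr, call)
    expect_lt(abs(area - A) / A, 0.02)
  }

  # linearity: doubling intensities doubles the area
  tr <- gaussianTrace(100, 10)
  call <- detectPeak(tr, 10, 0.5, 3)
  tr2 <- tr; tr2$intensity <- 2 * tr2$intensity
  call2 <- detectPeak(tr2, 10, 0.5, 3)
  expect_equal(integrateArea(tr2, call2), 2 * integrateArea(tr, call),
               tolerance = 1e-9)
})

test_that("noise-only traces rarely trigger a presence call", {
  set.seed(33)
  falsePos <- 0L
  for (rep in 1:100) {
    tr <- structure(data.frame(rt = seq(5, 15, 0.02),
                               intensity = runif(501, 0, 1)),
                    class = c("XicTrace", "data.frame"))
    if (detectPeak(tr, 10, 0.5, 3)$present) falsePos <- falsePos + 1L
  }
  expect_lte(falsePos / 100, 0.05)
})

test_that("RT-resolved co-windowed peptides are never cross-assigned", {
  set.seed(44)
  for (rep in 1:20) {
    run <- twoPeptideRun(seed = rep, rtA = 9, rtB = 11, noise = 0.01)
    trace <- extractXic(run, win)
    callA <- detectPeak(trace, 9, 0.5, 3)
    callB <- detectPeak(trace, 11, 0.5, 3)
    expect_lte(abs(callA$apexRt - 9), 0.5)
    expect_lte(abs(callB$apexRt - 11), 0.5)
  }
})

test_that("kinetics series average technical replicates per time point", {
  scn <- krasScenario()
  injected <- c(1, 2, 3, 4) * 100
  runs <- list()
  for (t in seq_along(injected))
    for (tech in 1:2)
      runs[[length(runs) + 1L]] <- simulateRun(
        c(KLVVGAVGV = injected[t]), seed = 10 * t + tech,
        chromCfg = scn$chromCfg, runId = sprintf("t%d_k%d", t, tech),
        timePointH = t, bioRep = 1L, techRep = tech)
  series <- kineticsSeries(runs, scn$window, refRt = 10,
                           label = "KLVVGAVGV")
  expect_equal(series$n_tech, rep(2L, 4))
  for (t in seq_along(injected))
    expect_lt(abs(series$area[series$time_point_h == t] - injected[t]) /
                injected[t], 0.02)

  # all-blank runs yield an all-zero series
  blanks <- lapply(1:3, function(t)
    simulateRun(numeric(0), seed = t, chromCfg = scn$chromCfg,
                runId = paste0("b", t), timePointH = t, bioRep = 1L,
                techRep = 1L))
  zero <- kineticsSeries(blanks, scn$window, refRt = 10)
  expect_true(all(zero$area == 0))
  expect_true(all(zero$n_present == 0))

  # duplicate design slots are a design error
  dup <- c(runs, runs[1])
  expect_error(kineticsSeries(dup, scn$window, 10), "duplicate")
})
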