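# Run code with a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv()))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed %% 2147483647))
  force(expr)
}

# documented sub-seed derivation: keeps every derived seed below 2^31
.subSeed <- function(seed, index) {
  (as.numeric(seed) * 1009 + as.numeric(index) * 9973) %% 2147483647
}

# ---- digestion time course -------------------------------------------------

#' Digestion time-course configuration
#'
#' Biphasic first-order substrate consumption
#' \eqn{S(t) = \exp(-k_1 \min(t, \tau) - k_2 \max(0, t - \tau))} with a
#' rate breakpoint at \eqn{\tau} hours (proteasomes change their catalytic
#' dynamics over time), and product formation tied to substrate
#' consumption, \eqn{P_i(t) = \alpha_i (1 - S(t))}, with one amplitude per
#' product in arbitrary area units. The default first-phase rate
#' \eqn{k_1 = \ln(4)/4 \approx 0.3466} per hour is calibrated so that a
#' quarter of the substrate remains after 4 h with \eqn{\tau = 4}; the
#' default \eqn{k_2 = 0.2} per hour makes a 20 h endpoint near-complete
#' (about 1% substrate remaining).
#'
#' @param products data.frame with columns \code{sequence},
#'   \code{amplitude} (area units, >= 0).
#' @param k1,k2 first-order rates per hour, >= 0.
#' @param tau rate breakpoint in hours, >= 0.
#' @param timePoints digestion time points in hours.
#' @return list of class \code{"DigestionSimConfig"}.
#' @export
digestionConfig <- function(products, k1 = log(4) / 4, k2 = 0.2, tau = 4,
                            timePoints = c(0, 1, 2, 3, 4)) {
  stopifnot(is.data.frame(products),
            all(c("sequence", "amplitude") %in% names(products)),
            all(products$amplitude >= 0), all(is.finite(products$amplitude)),
            k1 >= 0, k2 >= 0, tau >= 0)
  structure(list(products = products, k1 = k1, k2 = k2, tau = tau,
                 timePoints = sort(unique(timePoints))),
            class = "DigestionSimConfig")
}

#' Simulate a digestion time course
#'
#' Deterministic evaluation of the biphasic substrate-consumption model
#' and the tied product amounts at the configured time points.
#'
#' @param cfg a \code{\link{digestionConfig}}.
#' @param timePoints optional override of the configured time points.
#' @return list with \code{substrate} (data.frame \code{time_h},
#'   \code{fraction}) and \code{products} (long data.frame \code{time_h},
#'   \code{sequence}, \code{amount}).
#' @export
#' @examples
#' cfg <- digestionConfig(data.frame(sequence = "KLVVGAVGV",
#'                                   amplitude = 100))
#' simulateDigestion(cfg)$substrate   # fraction 0.25 at t = 4
simulateDigestion <- function(cfg, timePoints = cfg$timePoints) {
  stopifnot(inherits(cfg, "DigestionSimConfig"))
  if (any(timePoints < 0))
    stop("negative digestion time", call. = FALSE)
  S <- exp(-cfg$k1 * pmin(timePoints, cfg$tau) -
             cfg$k2 * pmax(0, timePoints - cfg$tau))
  products <- do.call(rbind, lapply(seq_len(nrow(cfg$products)), function(i)
    data.frame(time_h = timePoints, sequence = cfg$products$sequence[i],
               amount = cfg$products$amplitude[i] * (1 - S))))
  list(substrate = data.frame(time_h = timePoints, fraction = S),
       products = products)
}

# ---- MS2 spectrum simulator ------------------------------------------------

#' MS2 spectrum simulator configuration
#'
#' Noise model for simulated fragment spectra: each theoretical ion is
#' detected with probability \code{p} at its m/z perturbed by Gaussian
#' ppm jitter, with log-normal intensity; uniform random noise peaks are
#' added over the m/z range.
#'
#' @param p per-ion detection probability in [0, 1].
#' @param jitterPpm standard deviation of the m/z error in ppm (>= 0).
#' @param nNoise number of noise peaks.
#' @param ionMeanLog,ionSdLog log-normal intensity parameters for true
#'   ions.
#' @param noiseMeanLog,noiseSdLog log-normal intensity parameters for
#'   noise peaks.
#' @param mzRange m/z range for noise peaks; NULL spans the theoretical
#'   ions with 5% margin.
#' @return list of class \code{"SpectrumSimConfig"}.
#' @export
spectrumSimConfig <- function(p = 0.8, jitterPpm = 5, nNoise = 30L,
                              ionMeanLog = log(1000), ionSdLog = 0.5,
                              noiseMeanLog = log(50), noiseSdLog = 0.7,
                              mzRange = NULL) {
  stopifnot(p >= 0, p <= 1, jitterPpm >= 0, nNoise >= 0)
  structure(list(p = p, jitterPpm = jitterPpm, nNoise = as.integer(nNoise),
                 ionMeanLog = ionMeanLog, ionSdLog = ionSdLog,
                 noiseMeanLog = noiseMeanLog, noiseSdLog = noiseSdLog,
                 mzRange = mzRange),
            class = "SpectrumSimConfig")
}

#' Simulate an MS2 spectrum of a peptidoform
#'
#' @param sequence peptide sequence.
#' @param seed RNG seed; identical seeds give identical spectra.
#' @param simCfg a \code{\link{spectrumSimConfig}}.
#' @param fragCfg a \code{\link{fragmentConfig}}.
#' @param mods optional modification data.frame.
#' @param charge precursor charge for the spectrum header (default 2).
#' @param rt retention time to stamp on the spectrum, minutes.
#' @param id spectrum identifier.
#' @return A \linkS4class{Spectrum}.
#' @export
simulateMs2 <- function(sequence, seed, simCfg = spectrumSimConfig(),
                        fragCfg = fragmentConfig(), mods = NULL,
                        charge = 2L, rt = NA_real_,
                        id = paste0("sim_", sequence)) {
  frags <- theoreticalFragments(sequence, mods, fragCfg)
  .withSeed(seed, {
    detected <- stats::runif(nrow(frags)) < simCfg$p
    mz <- frags$mz[detected] *
      (1 + stats::rnorm(sum(detected), 0, simCfg$jitterPpm) * 1e-6)
    intensity <- stats::rlnorm(sum(detected), simCfg$ionMeanLog,
                               simCfg$ionSdLog)
    if (simCfg$nNoise > 0L) {
      rng <- simCfg$mzRange
      if (is.null(rng)) rng <- c(0.95 * min(frags$mz), 1.05 * max(frags$mz))
      mz <- c(mz, stats::runif(simCfg$nNoise, rng[1L], rng[2L]))
      intensity <- c(intensity,
                     stats::rlnorm(simCfg$nNoise, simCfg$noiseMeanLog,
                                   simCfg$noiseSdLog))
    }
    Spectrum(mz, intensity, id = id,
             precursorMz = precursorMz(sequence, charge, mods),
             precursorCharge = charge, rt = rt)
  })
}

# ---- chromatogram run simulator --------------------------------------------

#' Chromatogram simulator configuration
#'
#' Each peptide elutes as a Gaussian profile at its reference RT; the
#' amount passed to \code{\link{simulateRun}} is the chromatographic area
#' (intensity x minutes) of that profile. A small per-run RT jitter mimics
#' run-to-run chromatographic drift. The noise floor is a continuous low
#' baseline: every scan carries noise peaks whose intensities draw
#' uniformly between half the noise level and the noise level, at random
#' m/z positions spanning the extraction window, so blank chromatogram
#' regions show a shallow quasi-constant background rather than isolated
#' spikes. The default level is far below analyte peaks, so
#' quantification operates at high signal-to-noise, as in the emulated
#' experiments.
#'
#' @param peptides data.frame with columns \code{label}, \code{mz},
#'   \code{ref_rt} (minutes), \code{sigma} (Gaussian width, minutes, > 0).
#' @param scanSpacing scan interval in minutes (> 0; default 0.02).
#' @param rtRange run RT range in minutes.
#' @param rtJitterSd per-run RT drift standard deviation, minutes.
#' @param noiseLevel upper bound of the uniform noise-peak intensity.
#' @param noisePeaksPerScan noise peaks per scan.
#' @param noiseMzRange m/z range of noise peaks.
#' @return list of class \code{"ChromSimConfig"}.
#' @export
chromSimConfig <- function(peptides, scanSpacing = 0.02,
                           rtRange = c(5, 15), rtJitterSd = 0.03,
                           noiseLevel = 0.01, noisePeaksPerScan = 2L,
                           noiseMzRange = c(421, 422)) {
  stopifnot(is.data.frame(peptides),
            all(c("label", "mz", "ref_rt", "sigma") %in% names(peptides)),
            all(peptides$sigma > 0), scanSpacing > 0,
            length(rtRange) == 2L, rtRange[1L] < rtRange[2L],
            rtJitterSd >= 0, noiseLevel >= 0, noisePeaksPerScan >= 0)
  structure(list(peptides = peptides, scanSpacing = scanSpacing,
                 rtRange = rtRange, rtJitterSd = rtJitterSd,
                 noiseLevel = noiseLevel,
                 noisePeaksPerScan = as.integer(noisePeaksPerScan),
                 noiseMzRange = noiseMzRange),
            class = "ChromSimConfig")
}

#' Simulate one MS1 chromatogram run
#'
#' @param amounts named numeric vector: chromatographic area per peptide
#'   label (labels must appear in the config; missing or zero amounts
#'   contribute nothing).
#' @param seed RNG seed.
#' @param chromCfg a \code{\link{chromSimConfig}}.
#' @param runId,role,timePointH,bioRep,techRep design-slot labels, see
#'   \linkS4class{ChromatogramRun}.
#' @return A \linkS4class{ChromatogramRun}.
#' @export
simulateRun <- function(amounts, seed, chromCfg, runId = "run",
                        role = "kinetics", timePointH = NA_real_,
                        bioRep = NA_integer_, techRep = NA_integer_) {
  stopifnot(inherits(chromCfg, "ChromSimConfig"))
  unknown <- setdiff(names(amounts), chromCfg$peptides$label)
  if (length(unknown))
    stop("amounts for peptides absent from the chromatogram config: ",
         paste(unknown, collapse = ", "), call. = FALSE)
  rt <- seq(chromCfg$rtRange[1L], chromCfg$rtRange[2L],
            by = chromCfg$scanSpacing)
  .withSeed(seed, {
    rows <- list()
    for (k in seq_len(nrow(chromCfg$peptides))) {
      pep <- chromCfg$peptides[k, ]
      amt <- if (pep$label %in% names(amounts)) amounts[[pep$label]] else 0
      if (amt <= 0) next
      center <- pep$ref_rt + stats::rnorm(1, 0, chromCfg$rtJitterSd)
      sel <- which(abs(rt - center) <= 5 * pep$sigma)
      if (!length(sel)) next
      rows[[length(rows) + 1L]] <- data.frame(
        scan = sel, mz = pep$mz,
        intensity = amt * stats::dnorm(rt[sel], center, pep$sigma))
    }
    nNoise <- chromCfg$noisePeaksPerScan * length(rt)
    if (nNoise > 0L && chromCfg$noiseLevel > 0) {
      rows[[length(rows) + 1L]] <- data.frame(
        scan = rep(seq_along(rt), each = chromCfg$noisePeaksPerScan),
        mz = stats::runif(nNoise, chromCfg$noiseMzRange[1L],
                          chromCfg$noiseMzRange[2L]),
        intensity = stats::runif(nNoise, chromCfg$noiseLevel / 2,
                                 chromCfg$noiseLevel))
    }
    peaks <- if (length(rows)) do.call(rbind, rows) else
      data.frame(scan = integer(0), mz = numeric(0), intensity = numeric(0))
    ChromatogramRun(rt, peaks, runId = runId, role = role,
                    timePointH = timePointH, bioRep = bioRep,
                    techRep = techRep)
  })
}

# ---- experiment design and bundles -----------------------------------------

#' Kinetics experiment design
#'
#' The replicate layout of the emulated study: biological replicates x
#' time points x technical replicates, plus no-proteasome negative
#' controls (one per biological replicate) and synthetic-standard runs
#' (one per target peptide).
#'
#' @param nBio biological replicates (default 3).
#' @param timePoints digestion time points in hours (default 0-4 h).
#' @param nTech technical replicates per (bio, time) slot (default 3).
#' @param noProteasomeControls include negative-control runs (default
#'   TRUE).
#' @param standards include synthetic-standard reference runs (default
#'   TRUE).
#' @return list of class \code{"ExperimentDesign"}.
#' @export
experimentDesign <- function(nBio = 3L, timePoints = c(0, 1, 2, 3, 4),
                             nTech = 3L, noProteasomeControls = TRUE,
                             standards = TRUE) {
  stopifnot(nBio >= 1L, nTech >= 1L, length(timePoints) >= 1L)
  structure(list(nBio = as.integer(nBio), timePoints = sort(timePoints),
                 nTech = as.integer(nTech),
                 noProteasomeControls = isTRUE(noProteasomeControls),
                 standards = isTRUE(standards)),
            class = "ExperimentDesign")
}

#' Generate a full simulated run bundle for a kinetics design
#'
#' Simulates the digestion time course once, applies a per-biological-
#' replicate log-normal yield factor, and generates one chromatogram run
#' per (bio, time, tech) slot plus no-proteasome controls (all product
#' amounts zero) and synthetic-standard runs (one peptide each, fixed
#' amount). Per-run seeds are derived from the bundle seed as
#' \code{(seed * 1009 + runIndex * 9973) mod (2^31 - 1)}, so the whole
#' bundle is a pure function of (configs, seed).
#'
#' @param design an \code{\link{experimentDesign}}.
#' @param digestCfg a \code{\link{digestionConfig}} (its product sequences
#'   must match the chromatogram config's peptide labels).
#' @param chromCfg a \code{\link{chromSimConfig}}.
#' @param seed bundle RNG seed.
#' @param bioSdLog standard deviation (log scale) of the per-bio yield
#'   factor (default 0.1).
#' @param standardAmount chromatographic area injected in standard runs
#'   (default: the largest product amplitude).
#' @param dir optional directory: when given, each run is written as a
#'   scans CSV plus a \code{manifest.csv}.
#' @return list with \code{manifest} (data.frame \code{run_id},
#'   \code{role}, \code{bio}, \code{tech}, \code{time_point_h},
#'   \code{peptide}), \code{runs} (named list of
#'   \linkS4class{ChromatogramRun}), and \code{digestion}.
#' @export
generateDesignBundle <- function(design, digestCfg, chromCfg, seed,
                                 bioSdLog = 0.1, standardAmount = NULL,
                                 dir = NULL) {
  stopifnot(inherits(design, "ExperimentDesign"),
            inherits(digestCfg, "DigestionSimConfig"),
            inherits(chromCfg, "ChromSimConfig"))
  digestion <- simulateDigestion(digestCfg, design$timePoints)
  bioFactor <- .withSeed(.subSeed(seed, 0),
                         stats::rlnorm(design$nBio, 0, bioSdLog))
  if (is.null(standardAmount))
    standardAmount <- max(digestCfg$products$amplitude)
  runs <- list()
  manifest <- list()
  idx <- 0L
  addRun <- function(run, peptide = NA_character_) {
    runs[[run@runId]] <<- run
    manifest[[length(manifest) + 1L]] <<- data.frame(
      run_id = run@runId, role = run@role, bio = run@bioRep,
      tech = run@techRep, time_point_h = run@timePointH, peptide = peptide)
  }
  for (b in seq_len(design$nBio)) {
    for (t in design$timePoints) {
      amt <- digestion$products$amount[digestion$products$time_h == t]
      names(amt) <- digestion$products$sequence[
        digestion$products$time_h == t]
      amt <- amt * bioFactor[b]
      for (k in seq_len(design$nTech)) {
        idx <- idx + 1L
        addRun(simulateRun(amt, .subSeed(seed, idx), chromCfg,
                           runId = sprintf("bio%d_t%g_tech%d", b, t, k),
                           role = "kinetics", timePointH = t,
                           bioRep = b, techRep = k))
      }
    }
  }
  if (design$noProteasomeControls) {
    for (b in seq_len(design$nBio)) {
      idx <- idx + 1L
      addRun(simulateRun(numeric(0), .subSeed(seed, idx), chromCfg,
                         runId = sprintf("bio%d_noproteasome", b),
                         role = "control",
                         timePointH = max(design$timePoints),
                         bioRep = b, techRep = 1L))
    }
  }
  if (design$standards) {
    for (lab in chromCfg$peptides$label) {
      idx <- idx + 1L
      amt <- stats::setNames(standardAmount, lab)
      addRun(simulateRun(amt, .subSeed(seed, idx), chromCfg,
                         runId = sprintf("standard_%s", lab),
                         role = "standard"), peptide = lab)
    }
  }
  manifest <- do.call(rbind, manifest)
  rownames(manifest) <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    for (r in runs)
      writeScansCsv(r, file.path(dir, paste0(r@runId, ".csv")))
    utils::write.csv(manifest, file.path(dir, "manifest.csv"),
                     row.names = FALSE)
  }
  list(manifest = manifest, runs = runs, digestion = digestion)
}

# ---- hit-table simulator ---------------------------------------------------

#' Simulate a ranked hit table with known filter ground truth
#'
#' Builds per-scan hit lists whose acceptance outcome under the
#' score/q-value/delta rule is known by construction: top scores, q-values
#' and competitor score gaps are drawn from ranges that straddle the
#' configured thresholds, a small fraction of scans carries an exact tied
#' top score, and another small fraction sits exactly on the delta
#' boundaries. The expected decision is computed at generation time by
#' direct arithmetic on the drawn parameters.
#'
#' @param nScans number of scans.
#' @param seed RNG seed.
#' @param cfg the \code{\link{filterConfig}} whose thresholds define the
#'   ground truth.
#' @param splicedSeq,nonsplicedSeq sequences used for the generated hits.
#' @return list with \code{hits} (a filter-ready data.frame) and
#'   \code{truth} (data.frame \code{scan_id}, \code{expect_accept},
#'   \code{expect_sequence}, \code{expect_reason}).
#' @export
simulateHitTable <- function(nScans, seed, cfg = filterConfig(),
                             splicedSeq = "KLVVGAVGV",
                             nonsplicedSeq = "KLVVVGAVG") {
  .withSeed(seed, {
    hitRows <- list()
    truthRows <- list()
    for (i in seq_len(nScans)) {
      id <- sprintf("scan%05d", i)
      scenario <- stats::runif(1)
      topScore <- stats::runif(1, 5, 60)
      q <- stats::runif(1, 0, 0.08)
      if (scenario < 0.05) {
        # exact tied top score
        rows <- data.frame(
          scan_id = id, rank = c(1L, 1L),
          sequence = c(splicedSeq, nonsplicedSeq),
          category = c("spliced", "nonspliced"),
          ion_score = topScore, q_value = q)
        expect <- list(accept = FALSE, sequence = NA_character_,
                       reason = "ambiguous_tie")
      } else {
        spliced <- stats::runif(1) < 0.6
        boundary <- scenario < 0.10     # exact delta boundaries
        dSS <- if (boundary) cfg$deltaSplicedSpliced else
          stats::runif(1, 1, 40)
        dSN <- if (boundary) cfg$deltaSplicedNonspliced else
          stats::runif(1, 1, 60)
        hasSS <- spliced && stats::runif(1) < 0.8
        hasSN <- stats::runif(1) < 0.8
        top <- data.frame(
          scan_id = id, rank = 1L,
          sequence = if (spliced) splicedSeq else nonsplicedSeq,
          category = if (spliced) "spliced" else "nonspliced",
          ion_score = topScore, q_value = q)
        comp <- list()
        if (hasSS) comp[[length(comp) + 1L]] <- data.frame(
          scan_id = id, rank = NA_integer_, sequence = "KLVVGAVVG",
          category = "spliced", ion_score = topScore * (1 - dSS / 100),
          q_value = stats::runif(1, 0, 0.2))
        if (hasSN) comp[[length(comp) + 1L]] <- data.frame(
          scan_id = id, rank = NA_integer_, sequence = nonsplicedSeq,
          category = "nonspliced", ion_score = topScore * (1 - dSN / 100),
          q_value = stats::runif(1, 0, 0.2))
        rows <- rbind(top, do.call(rbind, comp))
        rows <- rows[order(-rows$ion_score), , drop = FALSE]
        rows$rank <- seq_len(nrow(rows))
        # ground truth by direct arithmetic on the drawn parameters
        expect <- if (topScore < cfg$scoreMin)
          list(accept = FALSE, sequence = NA_character_,
               reason = "below_score")
        else if (q > cfg$qMax)
          list(accept = FALSE, sequence = NA_character_,
               reason = "above_q")
        else if (spliced) {
          ssOk <- !hasSS || dSS >= cfg$deltaSplicedSpliced
          snOk <- !hasSN || dSN >= cfg$deltaSplicedNonspliced
          pass <- if (cfg$deltaCombine == "and") ssOk && snOk else
            ssOk || snOk
          if (pass)
            list(accept = TRUE, sequence = splicedSeq,
                 reason = NA_character_)
          else
            list(accept = FALSE, sequence = NA_character_,
                 reason = if (!snOk) "delta_sn_fail" else "delta_ss_fail")
        } else
          list(accept = TRUE, sequence = nonsplicedSeq,
               reason = NA_character_)
      }
      hitRows[[length(hitRows) + 1L]] <- rows
      truthRows[[length(truthRows) + 1L]] <- data.frame(
        scan_id = id, expect_accept = expect$accept,
        expect_sequence = expect$sequence, expect_reason = expect$reason)
    }
    list(hits = do.call(rbind, hitRows),
         truth = do.call(rbind, truthRows))
  })
}
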