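#' The KRAS 2-35 G12V substrate
#'
#' The 34-residue synthetic substrate polypeptide
#' TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT covering KRAS residues 2-35 with the
#' G12V mutation, the model system of this package. Protein coordinates
#' start at 2, so \code{"5-13"} denotes the non-spliced peptide KLVVVGAVG
#' and \code{"5-6/8-14"} the cis-spliced isobar KLVVGAVGV (reactants KL and
#' VVGAVGV, skipping V7).
#'
#' @return A \linkS4class{Substrate}.
#' @export
#' @examples
#' classifySequence("KLVVGAVGV", krasSubstrate())
krasSubstrate <- function() {
  Substrate("TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT",
            id = "KRAS_2-35_G12V", offset = 2L)
}

#' Default simulation scenario for the KRAS spliced/non-spliced pair
#'
#' Bundles the study conditions emulated by the simulators: the KRAS 2-35
#' G12V substrate; the isobaric product pair KLVVGAVGV (spliced, origin
#' 5-6/8-14) and KLVVVGAVG (non-spliced, origin 5-13), both observed as
#' doubly protonated precursors inside the m/z 421.275-421.875 extraction
#' window; RT-resolved reference elution (10 and 12 min, a 2 min gap well
#' beyond the 0.5 min RT tolerance); and a 3 biological x 5 time point
#' (0-4 h) x 3 technical replicate kinetics design. A co-eluting stress
#' scenario (RT gap 0.2 min) is available with
#' \code{scenario = "co_eluting"}.
#'
#' @param scenario \code{"rt_resolved"} (default) or \code{"co_eluting"}.
#' @return list with elements \code{substrate}, \code{products},
#'   \code{window}, \code{design}, \code{digestCfg}, \code{chromCfg},
#'   \code{rtTol}, \code{snrMin}.
#' @export
krasScenario <- function(scenario = c("rt_resolved", "co_eluting")) {
  scenario <- match.arg(scenario)
  spliced <- "KLVVGAVGV"
  nonspliced <- "KLVVVGAVG"
  rtB <- if (scenario == "rt_resolved") 12 else 10.2
  peptides <- data.frame(
    label = c(spliced, nonspliced),
    mz = c(precursorMz(spliced, 2L), precursorMz(nonspliced, 2L)),
    ref_rt = c(10, rtB),
    sigma = 0.1)
  list(substrate = krasSubstrate(),
       products = data.frame(sequence = c(spliced, nonspliced),
                             amplitude = c(3000, 5000),
                             category = c("spliced", "nonspliced")),
       window = mzWindow(421.275, 421.875),
       design = experimentDesign(),
       digestCfg = digestionConfig(
         data.frame(sequence = c(spliced, nonspliced),
                    amplitude = c(3000, 5000))),
       chromCfg = chromSimConfig(peptides),
       rtTol = 0.5, snrMin = 3)
}

#' Run the full identification/quantification pipeline on a run bundle
#'
#' Executes, on a simulated (or loaded) bundle of chromatogram runs, the
#' analysis chain applied to in vitro digestion kinetics:
#' \enumerate{
#'   \item measure each peptide's reference RT as the XIC apex of its
#'     synthetic-standard run;
#'   \item test whether the reference RTs are chromatographically
#'     resolved;
#'   \item assemble the XIC kinetics series (extract, detect at the
#'     reference RT, integrate; technical replicates averaged) per
#'     peptide;
#'   \item call presence/absence in the no-proteasome control runs;
#'   \item confirm identity by MS2: at each time point with non-zero
#'     simulated product amount, simulate a fragment spectrum of the true
#'     peptide, score it against both isobaric candidates with the
#'     surrogate match score, and count diagnostic-ion support; a peptide
#'     is identified at a time point iff its XIC peak is present, its
#'     match score reaches the filter's score threshold, and the
#'     diagnostic verdict picks the true candidate.
#' }
#'
#' @param bundle a \code{\link{generateDesignBundle}} result.
#' @param scn a \code{\link{krasScenario}}-style scenario list.
#' @param seed RNG seed for the MS2 confirmation spectra.
#' @param tol MS2 matching tolerance (default the 20 ppm preset).
#' @param fragCfg fragment configuration for annotation.
#' @param scoreMin identification score threshold (default 20, as in the
#'   filter).
#' @return list with \code{referenceRts}, \code{rtResolved},
#'   \code{kinetics} (named list of \code{\link{kineticsSeries}}),
#'   \code{controls} (data.frame of presence calls),
#'   \code{identifications} (data.frame \code{sequence},
#'   \code{time_point_h}, \code{xic_present}, \code{score},
#'   \code{diagnostic_verdict_true}, \code{identified}).
#' @export
runSplicePipeline <- function(bundle, scn = krasScenario(), seed = 1,
                              tol = msmsTolerancePreset("QE-HF"),
                              fragCfg = fragmentConfig(),
                              scoreMin = filterConfig()$scoreMin) {
  runs <- bundle$runs
  peptides <- scn$chromCfg$peptides
  stdRuns <- Filter(function(r) runRole(r) == "standard", runs)
  refRts <- vapply(peptides$label, function(lab) {
    std <- Filter(function(r)
      identical(r@runId, sprintf("standard_%s", lab)), stdRuns)
    if (!length(std)) return(NA_real_)
    trace <- extractXic(std[[1L]], scn$window)
    trace$rt[which.max(trace$intensity)]
  }, numeric(1))

  resolved <- if (nrow(peptides) >= 2L)
    rtResolved(refRts[1L], refRts[2L], scn$rtTol) else NA

  kin <- lapply(peptides$label, function(lab)
    kineticsSeries(runs, scn$window, refRts[[lab]],
                   rtTol = scn$rtTol, snrMin = scn$snrMin, label = lab))
  names(kin) <- peptides$label

  ctrlRuns <- Filter(function(r) runRole(r) == "control", runs)
  controls <- do.call(rbind, lapply(ctrlRuns, function(r) {
    trace <- extractXic(r, scn$window)
    do.call(rbind, lapply(peptides$label, function(lab) {
      call <- detectPeak(trace, refRts[[lab]], scn$rtTol, scn$snrMin)
      data.frame(run_id = r@runId, peptide = lab, present = call$present)
    }))
  }))
  rownames(controls) <- NULL

  # MS2 identity confirmation against the isobaric candidate pair
  amounts <- bundle$digestion$products
  candA <- peptides$label[1L]
  candB <- peptides$label[2L]
  identRows <- list()
  for (i in seq_len(nrow(amounts))) {
    seqTrue <- amounts$sequence[i]
    t <- amounts$time_h[i]
    hasProduct <- amounts$amount[i] > 0
    series <- kin[[seqTrue]]
    xicPresent <- any(series$n_present[series$time_point_h == t] > 0)
    score <- 0
    verdictTrue <- FALSE
    if (hasProduct) {
      sp <- simulateMs2(seqTrue, .subSeed(seed, i), rt = NA_real_,
                        fragCfg = fragCfg)
      score <- matchScore(sp, seqTrue, tol, fragCfg = fragCfg)
      rep <- diagnosticIons(candA, candB, tol, fragCfg = fragCfg)
      rep <- supportInSpectrum(sp, rep, tol)
      verdictTrue <- (rep$verdict == "A" && seqTrue == candA) ||
        (rep$verdict == "B" && seqTrue == candB)
    }
    identRows[[length(identRows) + 1L]] <- data.frame(
      sequence = seqTrue, time_point_h = t, xic_present = xicPresent,
      score = score, diagnostic_verdict_true = verdictTrue,
      identified = hasProduct && xicPresent && score >= scoreMin &&
        verdictTrue)
  }
  identifications <- do.call(rbind, identRows)

  list(referenceRts = refRts, rtResolved = resolved, kinetics = kin,
       controls = controls, identifications = identifications)
}
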