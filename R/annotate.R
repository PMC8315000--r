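#' Mass tolerance
#'
#' A matching window around a theoretical m/z value, either relative (ppm)
#' or absolute (Da). An observed peak at \code{obs} matches theoretical
#' \code{t} iff \code{|obs - t| <= t * value * 1e-6} (ppm) or
#' \code{|obs - t| <= value} (Da). Two instrument presets mirror common
#' Orbitrap settings: \code{msmsTolerancePreset("QE-HF")} gives 20 ppm and
#' \code{msmsTolerancePreset("Exploris")} gives 0.02 Da.
#'
#' @param value positive tolerance value.
#' @param mode \code{"ppm"} or \code{"Da"}.
#' @return A list of class \code{"Tolerance"}.
#' @export
tolerance <- function(value, mode = c("ppm", "Da")) {
  mode <- match.arg(mode)
  stopifnot(is.numeric(value), length(value) == 1L, value > 0)
  structure(list(value = value, mode = mode), class = "Tolerance")
}

#' @rdname tolerance
#' @param preset \code{"QE-HF"} (MS2 20 ppm) or \code{"Exploris"}
#'   (MS2 0.02 Da; also applies to Lumos-style measurements).
#' @export
msmsTolerancePreset <- function(preset = c("QE-HF", "Exploris")) {
  preset <- match.arg(preset)
  if (preset == "QE-HF") tolerance(20, "ppm") else tolerance(0.02, "Da")
}

# half-width of the matching window at theoretical m/z t
.tolWindow <- function(t, tol) {
  if (tol$mode == "ppm") t * tol$value * 1e-6 else rep(tol$value, length(t))
}

#' Annotate an MS2 spectrum with theoretical fragment ions
#'
#' Greedy deterministic assignment: theoretical ions are processed in
#' ascending m/z; each ion takes the nearest not-yet-used peak within the
#' tolerance window. Each theoretical ion matches at most one peak and each
#' peak is used at most once.
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param sequence peptide sequence to annotate against.
#' @param tol a \code{\link{tolerance}}.
#' @param mods optional modification data.frame.
#' @param fragCfg a \code{\link{fragmentConfig}}.
#' @return A list of class \code{"AnnotationResult"}: \code{matches}
#'   (data.frame label/series/index/charge/loss/mz_theo/mz_obs/intensity),
#'   \code{unmatchedIons}, \code{unmatchedPeaks}, \code{matchedIonCount},
#'   \code{matchedIntensityFraction}, \code{nTheoretical}.
#' @export
annotateSpectrum <- function(spectrum, sequence, tol, mods = NULL,
                             fragCfg = fragmentConfig()) {
  stopifnot(is(spectrum, "Spectrum"), inherits(tol, "Tolerance"))
  frags <- theoreticalFragments(sequence, mods, fragCfg)   # sorted by mz
  p <- spectrum@peaks
  used <- rep(FALSE, nrow(p))
  obsIdx <- rep(NA_integer_, nrow(frags))
  if (nrow(p)) {
    for (i in seq_len(nrow(frags))) {
      w <- .tolWindow(frags$mz[i], tol)
      d <- abs(p[, 1L] - frags$mz[i])
      cand <- which(!used & d <= w)
      if (length(cand)) {
        pick <- cand[which.min(d[cand])]
        used[pick] <- TRUE
        obsIdx[i] <- pick
      }
    }
  }
  hit <- !is.na(obsIdx)
  matches <- cbind(frags[hit, , drop = FALSE],
                   mz_obs = p[obsIdx[hit], 1L],
                   intensity = p[obsIdx[hit], 2L])
  names(matches)[names(matches) == "mz"] <- "mz_theo"
  rownames(matches) <- NULL
  totalInt <- sum(p[, 2L])
  structure(list(
    matches = matches,
    unmatchedIons = frags[!hit, , drop = FALSE],
    unmatchedPeaks = as.data.frame(p[!used, , drop = FALSE]),
    matchedIonCount = sum(hit),
    matchedIntensityFraction = if (totalInt > 0)
      sum(p[used, 2L]) / totalInt else 0,
    nTheoretical = nrow(frags)),
    class = "AnnotationResult")
}

#' Compare fragment annotation between two spectra of the same peptidoform
#'
#' Mirrors the red/blue peak comparison between a digestion spectrum and
#' its synthetic-standard counterpart: an ion is \emph{shared} if matched
#' in both spectra ("red"), and \emph{unique} to a spectrum if matched in
#' exactly one ("blue").
#'
#' @param spectrum1,spectrum2 two \linkS4class{Spectrum} objects.
#' @inheritParams annotateSpectrum
#' @return list with character vectors \code{shared}, \code{uniqueTo1},
#'   \code{uniqueTo2} of ion labels, plus both \code{AnnotationResult}s.
#' @export
spectraAgreement <- function(spectrum1, spectrum2, sequence, tol,
                             mods = NULL, fragCfg = fragmentConfig()) {
  a1 <- annotateSpectrum(spectrum1, sequence, tol, mods, fragCfg)
  a2 <- annotateSpectrum(spectrum2, sequence, tol, mods, fragCfg)
  l1 <- a1$matches$label
  l2 <- a2$matches$label
  list(shared = intersect(l1, l2),
       uniqueTo1 = setdiff(l1, l2),
       uniqueTo2 = setdiff(l2, l1),
       annotation1 = a1, annotation2 = a2)
}

#' Diagnostic fragment ions between two isobaric candidates
#'
#' Partitions the theoretical ions of each candidate into mass-shared ions
#' (some ion of the other candidate lies within the tolerance window) and
#' diagnostic ions (no counterpart within tolerance). For isobaric
#' sequence isomers the diagnostic ions are exactly those fragments whose
#' residue composition differs between the two sequences.
#'
#' @param sequenceA,sequenceB the two candidate sequences.
#' @param tol a \code{\link{tolerance}}.
#' @param modsA,modsB optional per-candidate modifications.
#' @param fragCfg a \code{\link{fragmentConfig}}.
#' @return list of class \code{"DiscriminationReport"}: \code{candidateA},
#'   \code{candidateB}, \code{sharedA}/\code{sharedB} (data.frames of
#'   mass-shared ions), \code{diagnosticA}/\code{diagnosticB}, and NA
#'   placeholders for the spectrum-support fields filled in by
#'   \code{\link{supportInSpectrum}}.
#' @export
#' @examples
#' rep <- diagnosticIons("KLVVGAVGV", "KLVVVGAVG", tolerance(0.02, "Da"),
#'                       fragCfg = fragmentConfig(maxCharge = 1,
#'                                                losses = "none"))
#' sort(rep$diagnosticA$label)   # b5 b6 b8 y1 y3 y4
diagnosticIons <- function(sequenceA, sequenceB, tol, modsA = NULL,
                           modsB = NULL, fragCfg = fragmentConfig()) {
  fa <- theoreticalFragments(sequenceA, modsA, fragCfg)
  fb <- theoreticalFragments(sequenceB, modsB, fragCfg)
  sharedIn <- function(f, other) {
    vapply(f$mz, function(t)
      any(abs(other$mz - t) <= .tolWindow(t, tol)), logical(1))
  }
  sa <- sharedIn(fa, fb)
  sb <- sharedIn(fb, fa)
  structure(list(
    candidateA = sequenceA, candidateB = sequenceB,
    sharedA = fa[sa, , drop = FALSE], sharedB = fb[sb, , drop = FALSE],
    diagnosticA = fa[!sa, , drop = FALSE],
    diagnosticB = fb[!sb, , drop = FALSE],
    supportA = NA_integer_, supportB = NA_integer_,
    verdict = NA_character_, rtResolved = NA),
    class = "DiscriminationReport")
}

#' Count observed diagnostic-ion support in a spectrum
#'
#' For each candidate's diagnostic ions, counts how many have an observed
#' peak within tolerance; the verdict names the candidate with strictly
#' more diagnostic support and is \code{"ambiguous"} on ties (including
#' when only shared-mass peaks are present).
#'
#' @param spectrum a \linkS4class{Spectrum}.
#' @param report a \code{\link{diagnosticIons}} report.
#' @param tol a \code{\link{tolerance}}.
#' @return The report with \code{supportA}, \code{supportB} and
#'   \code{verdict} (\code{"A"}, \code{"B"} or \code{"ambiguous"}) filled.
#' @export
supportInSpectrum <- function(spectrum, report, tol) {
  stopifnot(is(spectrum, "Spectrum"),
            inherits(report, "DiscriminationReport"))
  mz <- spectrum@peaks[, 1L]
  count <- function(f) {
    if (!nrow(f) || !length(mz)) return(0L)
    sum(vapply(f$mz, function(t)
      any(abs(mz - t) <= .tolWindow(t, tol)), logical(1)))
  }
  report$supportA <- count(report$diagnosticA)
  report$supportB <- count(report$diagnosticB)
  report$verdict <- if (report$supportA > report$supportB) "A"
                    else if (report$supportB > report$supportA) "B"
                    else "ambiguous"
  report
}

#' Surrogate peptide-spectrum match score
#'
#' A documented stand-in for a search engine's ion score:
#' \eqn{-10 \log_{10}} of the binomial tail probability of matching at
#' least \eqn{k} of the \eqn{m} theoretical ions by chance, where the
#' per-ion random-match probability is (number of peaks x matching window
#' width) / spectrum m/z span, clamped to (0, 1). Empty spectra and
#' zero-match annotations score 0. Downstream filtering treats scores as an
#' opaque column, so externally computed scores can be substituted.
#'
#' @inheritParams annotateSpectrum
#' @return Non-negative score.
#' @export
matchScore <- function(spectrum, sequence, tol, mods = NULL,
                       fragCfg = fragmentConfig()) {
  p <- spectrum@peaks
  if (nrow(p) < 2L) return(0)
  ann <- annotateSpectrum(spectrum, sequence, tol, mods, fragCfg)
  k <- ann$matchedIonCount
  if (k == 0L) return(0)
  m <- ann$nTheoretical
  span <- max(p[, 1L]) - min(p[, 1L])
  if (span <= 0) return(0)
  theoMz <- c(ann$matches$mz_theo, ann$unmatchedIons$mz)
  width <- 2 * mean(.tolWindow(theoMz, tol))
  prob <- min(max(nrow(p) * width / span, 1e-12), 1 - 1e-12)
  tail <- stats::pbinom(k - 1L, m, prob, lower.tail = FALSE)
  max(0, -10 * log10(max(tail, .Machine$double.xmin)))
}

#' Are two retention times chromatographically resolved?
#'
#' TRUE iff the absolute RT difference strictly exceeds the tolerance
#' (boundary counts as unresolved).
#'
#' @param rtA,rtB retention times in minutes.
#' @param rtTol RT tolerance in minutes (> 0).
#' @return logical flag.
#' @export
rtResolved <- function(rtA, rtB, rtTol) {
  stopifnot(rtTol > 0)
  abs(rtA - rtB) > rtTol
}
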