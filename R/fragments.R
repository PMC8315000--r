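#' Fragment-ion generation configuration
#'
#' Which backbone ion series, neutral losses and charge states to generate.
#' Ammonia loss (-17.026549 Da) is on by default because it is the loss
#' routinely annotated in digestion MS2 spectra of these peptides; water
#' loss is available behind \code{waterLoss = TRUE} but off by default.
#'
#' @param series character subset of \code{c("b", "a", "y")}.
#' @param losses character subset of \code{c("none", "NH3")}.
#' @param maxCharge maximum fragment charge state (default 2).
#' @param waterLoss also generate H2O-loss ions (default FALSE).
#' @return A validated list of class \code{"FragmentConfig"}.
#' @export
fragmentConfig <- function(series = c("b", "a", "y"),
                           losses = c("none", "NH3"),
                           maxCharge = 2L, waterLoss = FALSE) {
  stopifnot(all(series %in% c("b", "a", "y")), length(series) >= 1L,
            all(losses %in% c("none", "NH3")), length(losses) >= 1L,
            maxCharge >= 1L)
  if (isTRUE(waterLoss)) losses <- c(losses, "H2O")
  structure(list(series = series, losses = unique(losses),
                 maxCharge = as.integer(maxCharge)),
            class = "FragmentConfig")
}

.modDeltaByPos <- function(n, mods) {
  delta <- numeric(n)
  if (!is.null(mods) && nrow(mods)) {
    if (any(mods$pos < 1L | mods$pos > n))
      stop("modification position outside the peptide", call. = FALSE)
    if (anyDuplicated(mods$pos))
      stop("more than one modification on a residue", call. = FALSE)
    delta[mods$pos] <- mods$delta
  }
  delta
}

#' Monoisotopic neutral mass of a peptidoform
#'
#' Sum of residue monoisotopic masses plus one water plus any variable
#' modification deltas.
#'
#' @param sequence peptide string (empty string gives the mass of water).
#' @param mods optional modification data.frame with columns \code{pos},
#'   \code{name}, \code{delta}, as produced by
#'   \code{\link{expandModifications}}.
#' @return Neutral monoisotopic mass in Da.
#' @export
#' @examples
#' neutralMass("KLVVGAVGV")   # 840.54329
#' neutralMass("KLVVGAVGV") == neutralMass("KLVVVGAVG")  # isobaric pair
neutralMass <- function(sequence, mods = NULL) {
  if (identical(sequence, "")) {
    if (!is.null(mods) && nrow(mods))
      stop("modifications on an empty peptide", call. = FALSE)
    return(.MASS_WATER)
  }
  letters <- .checkAlphabet(sequence)
  sum(.MONO_RESIDUE[letters]) + .MASS_WATER +
    sum(.modDeltaByPos(length(letters), mods))
}

#' Precursor m/z of a peptidoform at a given charge
#'
#' \eqn{(M + z \cdot m_p) / z} with \eqn{m_p} the proton mass.
#'
#' @inheritParams neutralMass
#' @param charge precursor charge state, integer >= 1.
#' @return m/z in Da per charge.
#' @export
#' @examples
#' precursorMz("KLVVGAVGV", 2)   # 421.27892, inside 421.275-421.875
precursorMz <- function(sequence, charge, mods = NULL) {
  charge <- as.integer(charge)
  if (length(charge) != 1L || is.na(charge) || charge < 1L)
    stop("charge must be a positive integer", call. = FALSE)
  (neutralMass(sequence, mods) + charge * .MASS_PROTON) / charge
}

.ionLabel <- function(series, index, loss, charge) {
  paste0(series, index,
         ifelse(loss == "NH3", "*", ifelse(loss == "H2O", "o", "")),
         vapply(charge, function(z)
           if (z >= 2L) strrep("+", z) else "", character(1)))
}

#' Theoretical b-, a- and y-fragment ions
#'
#' For a peptide of n residues, generates ions at indices 1..n-1 for each
#' requested series, neutral loss and charge state. b ions are protonated
#' N-terminal prefixes, a ions are b minus CO, y ions are protonated
#' C-terminal suffixes plus water. Ammonia loss subtracts 17.026549 Da from
#' the fragment neutral mass. Variable modifications shift exactly the
#' fragments containing the modified residue.
#'
#' @inheritParams neutralMass
#' @param cfg a \code{\link{fragmentConfig}}.
#' @return data.frame with columns \code{label} (grammar: series+index,
#'   \code{"*"} iff NH3 loss, \code{"++"} iff doubly charged), \code{series},
#'   \code{index}, \code{charge}, \code{loss}, \code{mz}, sorted by
#'   \code{mz}.
#' @export
#' @examples
#' fr <- theoreticalFragments("KLVVGAVGV",
#'                            cfg = fragmentConfig(maxCharge = 1,
#'                                                 losses = "none"))
#' fr[fr$label == "b2", "mz"]   # 242.18631
theoreticalFragments <- function(sequence, mods = NULL,
                                 cfg = fragmentConfig()) {
  letters <- .checkAlphabet(sequence)
  n <- length(letters)
  if (n < 2L)
    stop("fragmentation requires a peptide of length >= 2", call. = FALSE)
  res <- .MONO_RESIDUE[letters] + .modDeltaByPos(n, mods)
  prefix <- cumsum(res)[-n]             # prefix[i] = first i residues
  suffix <- cumsum(rev(res))[-n]        # suffix[i] = last i residues

  neutralBySeries <- list(
    b = prefix,
    a = prefix - .MASS_CO,
    y = suffix + .MASS_WATER)
  lossDelta <- c(none = 0, NH3 = .MASS_NH3, H2O = .MASS_WATER)

  out <- list()
  for (ser in cfg$series) {
    base <- neutralBySeries[[ser]]
    for (loss in cfg$losses) {
      neutral <- base - lossDelta[[loss]]
      for (z in seq_len(cfg$maxCharge)) {
        out[[length(out) + 1L]] <- data.frame(
          label = .ionLabel(ser, seq_len(n - 1L), loss, z),
          series = ser, index = seq_len(n - 1L), charge = z, loss = loss,
          mz = (neutral + z * .MASS_PROTON) / z)
      }
    }
  }
  out <- do.call(rbind, out)
  out <- out[order(out$mz), , drop = FALSE]
  rownames(out) <- NULL
  out
}
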