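# Monoisotopic residue masses (Da), fixed at 6 decimal places so that tests
# can pin exact expected values. Residue mass = amino acid minus water.
.MONO_RESIDUE <- c(
  G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
  V = 99.068414, T = 101.047678, C = 103.009185, L = 113.084064,
  I = 113.084064, N = 114.042927, D = 115.026943, Q = 128.058578,
  K = 128.094963, E = 129.042593, M = 131.040485, H = 137.058912,
  F = 147.068414, R = 156.101111, Y = 163.063329, W = 186.079313
)

.MASS_WATER   <- 18.010565
.MASS_PROTON  <- 1.0072765
.MASS_NH3     <- 17.026549
.MASS_CO      <- 27.994915

# Variable modification mass shifts (Da)
.MOD_OXIDATION   <- 15.994915   # M
.MOD_DEAMIDATION <- 0.984016    # N, Q

#' Monoisotopic residue mass table
#'
#' Monoisotopic masses of the 20 canonical amino-acid residues (residue =
#' amino acid minus water), in Daltons, fixed to six decimal places.
#'
#' @return Named numeric vector of length 20.
#' @export
#' @examples
#' residueMasses()[["G"]]
residueMasses <- function() .MONO_RESIDUE

#' Physical mass constants
#'
#' Monoisotopic masses (Da) of water, the proton, ammonia and carbon
#' monoxide, used throughout the fragment-ion arithmetic.
#'
#' @return Named numeric vector with elements \code{water}, \code{proton},
#'   \code{ammonia}, \code{co}.
#' @export
massConstants <- function() {
  c(water = .MASS_WATER, proton = .MASS_PROTON,
    ammonia = .MASS_NH3, co = .MASS_CO)
}

#' Variable modification mass shifts
#'
#' Mass shifts (Da) of the variable modifications considered when expanding
#' peptidoforms: methionine oxidation and asparagine/glutamine deamidation.
#'
#' @return Named numeric vector with elements \code{oxidation} and
#'   \code{deamidation}.
#' @export
modificationDeltas <- function() {
  c(oxidation = .MOD_OXIDATION, deamidation = .MOD_DEAMIDATION)
}

.checkAlphabet <- function(sequence, what = "sequence") {
  if (length(sequence) != 1L || is.na(sequence) || !nzchar(sequence))
    stop(what, " must be a single non-empty string", call. = FALSE)
  letters <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  bad <- setdiff(unique(letters), names(.MONO_RESIDUE))
  if (length(bad))
    stop(what, " contains non-canonical letters: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(letters)
}
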