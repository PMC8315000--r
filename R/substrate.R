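#' Substrate polypeptide with protein-coordinate numbering
#'
#' An S4 container for a substrate polypeptide sequence together with the
#' full-protein coordinate of its first residue. The KRAS 2-35 G12V
#' substrate, for instance, carries \code{offset = 2}: substrate residue 1
#' is protein residue 2, so substrate residue \eqn{k} has protein coordinate
#' \eqn{offset + k - 1}. All enumeration output uses protein coordinates.
#'
#' @slot id single character identifier.
#' @slot sequence uppercase amino-acid string over the 20 canonical letters.
#' @slot offset integer >= 1, protein coordinate of the first residue.
#'
#' @name Substrate-class
#' @aliases Substrate-class
#' @exportClass Substrate
setClass("Substrate",
  slots = c(id = "character", sequence = "character", offset = "integer"))

setValidity("Substrate", function(object) {
  msg <- character(0)
  if (length(object@id) != 1L || is.na(object@id))
    msg <- c(msg, "id must be a single string")
  ok <- tryCatch({ .checkAlphabet(object@sequence, "sequence"); TRUE },
                 error = function(e) conditionMessage(e))
  if (!isTRUE(ok)) msg <- c(msg, ok)
  if (length(object@offset) != 1L || is.na(object@offset) ||
      object@offset < 1L)
    msg <- c(msg, "offset must be a single integer >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Substrate
#'
#' @param sequence uppercase amino-acid string.
#' @param id identifier (default \code{"substrate"}).
#' @param offset protein coordinate of the first residue (1-based; default 1).
#' @return A \linkS4class{Substrate} object.
#' @export
#' @examples
#' Substrate("TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT", id = "KRAS_2-35_G12V",
#'           offset = 2)
Substrate <- function(sequence, id = "substrate", offset = 1L) {
  new("Substrate", id = as.character(id),
      sequence = toupper(as.character(sequence)),
      offset = as.integer(offset))
}

#' @describeIn Substrate-class substrate identifier
#' @param x a \code{Substrate}.
#' @export
substrateId <- function(x) x@id

#' @describeIn Substrate-class substrate amino-acid sequence
#' @export
substrateSeq <- function(x) x@sequence

#' @describeIn Substrate-class protein coordinate of the first residue
#' @export
numberingOffset <- function(x) x@offset

#' @describeIn Substrate-class number of residues
#' @export
substrateLength <- function(x) nchar(x@sequence)

# protein coordinate <-> substrate-local index
.toLocal <- function(x, coord) coord - x@offset + 1L
.toProtein <- function(x, local) x@offset + local - 1L

setMethod("show", "Substrate", function(object) {
  cat("Substrate '", object@id, "' (", nchar(object@sequence),
      " residues, protein coordinates ", object@offset, "-",
      object@offset + nchar(object@sequence) - 1L, ")\n", sep = "")
  cat("  ", object@sequence, "\n", sep = "")
})

#' Read a substrate from a single-record FASTA file
#'
#' @param path path to a FASTA file containing exactly one record.
#' @param offset protein coordinate of the first residue (default 1).
#' @return A \linkS4class{Substrate}; the FASTA header becomes the id.
#' @export
readSubstrateFasta <- function(path, offset = 1L) {
  set <- Biostrings::readAAStringSet(path)
  if (length(set) != 1L)
    stop("expected exactly one FASTA record, found ", length(set),
         call. = FALSE)
  Substrate(as.character(set[[1L]]), id = names(set)[1L], offset = offset)
}
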