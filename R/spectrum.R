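#' Centroided MS2 spectrum
#'
#' A peak list (m/z, intensity) with precursor information and retention
#' time in minutes. Peaks are kept sorted by m/z and intensities must be
#' non-negative.
#'
#' @slot id scan title / identifier.
#' @slot precursorMz precursor m/z (NA if unknown).
#' @slot precursorCharge precursor charge (NA if unknown).
#' @slot rt retention time in minutes (NA if unknown).
#' @slot peaks two-column numeric matrix (\code{mz}, \code{intensity}).
#'
#' @name Spectrum-class
#' @aliases Spectrum-class
#' @exportClass Spectrum
setClass("Spectrum",
  slots = c(id = "character", precursorMz = "numeric",
            precursorCharge = "integer", rt = "numeric", peaks = "matrix"))

setValidity("Spectrum", function(object) {
  msg <- character(0)
  p <- object@peaks
  if (!is.numeric(p) || ncol(p) != 2L)
    msg <- c(msg, "peaks must be a two-column numeric matrix")
  else {
    if (nrow(p) && is.unsorted(p[, 1L]))
      msg <- c(msg, "peaks must be sorted by m/z")
    if (nrow(p) && any(p[, 2L] < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param mz,intensity numeric vectors of equal length (peaks are sorted by
#'   m/z on construction).
#' @param id scan identifier.
#' @param precursorMz,precursorCharge,rt precursor m/z, charge and retention
#'   time in minutes (NA when unknown).
#' @return A \linkS4class{Spectrum}.
#' @export
Spectrum <- function(mz = numeric(0), intensity = numeric(0),
                     id = "spectrum", precursorMz = NA_real_,
                     precursorCharge = NA_integer_, rt = NA_real_) {
  stopifnot(length(mz) == length(intensity))
  o <- order(mz)
  peaks <- cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
  new("Spectrum", id = as.character(id),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      rt = as.numeric(rt), peaks = peaks)
}

#' @describeIn Spectrum-class peak table as a data.frame (mz, intensity)
#' @param x a \code{Spectrum}.
#' @export
peakTable <- function(x) as.data.frame(x@peaks)

#' @describeIn Spectrum-class scan identifier
#' @export
spectrumId <- function(x) x@id

#' @describeIn Spectrum-class precursor m/z
#' @export
spectrumPrecursorMz <- function(x) x@precursorMz

#' @describeIn Spectrum-class precursor charge
#' @export
spectrumPrecursorCharge <- function(x) x@precursorCharge

#' @describeIn Spectrum-class retention time in minutes
#' @export
retentionTime <- function(x) x@rt

setMethod("show", "Spectrum", function(object) {
  cat("Spectrum '", object@id, "': ", nrow(object@peaks), " peaks",
      sep = "")
  if (!is.na(object@precursorMz))
    cat(sprintf(", precursor %.5f", object@precursorMz))
  if (!is.na(object@precursorCharge))
    cat(" (", object@precursorCharge, "+)", sep = "")
  if (!is.na(object@rt)) cat(sprintf(", RT %.2f min", object@rt))
  cat("\n")
})

# ---- MGF I/O ---------------------------------------------------------------

#' Read and write Mascot generic format (MGF) peak lists
#'
#' The dialect is the usual BEGIN IONS / TITLE / PEPMASS / CHARGE /
#' RTINSECONDS block structure with one "mz intensity" pair per line.
#' CHARGE values like \code{"2+"} are parsed as 2; RTINSECONDS is converted
#' to minutes internally and back to seconds on write.
#'
#' @param path file path.
#' @return \code{readMgf}: a list of \linkS4class{Spectrum} objects.
#' @export
readMgf <- function(path) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF: unbalanced BEGIN IONS/END IONS in ", path,
         call. = FALSE)
  lapply(seq_along(begins), function(k) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    isKey <- grepl("=", block, fixed = TRUE)
    keys <- block[isKey]
    kv <- sub("^[^=]*=", "", keys)                 # split on the first "="
    names(kv) <- sub("=.*$", "", keys)
    getv <- function(key) if (key %in% names(kv)) kv[[key]] else NA
    title <- getv("TITLE")
    pep <- getv("PEPMASS")
    pepmz <- if (is.na(pep)) NA_real_ else
      as.numeric(strsplit(trimws(pep), "[ \t]+")[[1L]][1L])
    chg <- getv("CHARGE")
    charge <- if (is.na(chg)) NA_integer_ else
      as.integer(sub("\\+$", "", trimws(chg)))
    rts <- getv("RTINSECONDS")
    rt <- if (is.na(rts)) NA_real_ else as.numeric(rts) / 60
    pk <- block[!isKey]
    pk <- pk[nzchar(trimws(pk))]
    if (length(pk)) {
      parts <- strsplit(trimws(pk), "[ \t]+")
      mz <- as.numeric(vapply(parts, `[`, character(1), 1L))
      it <- as.numeric(vapply(parts, `[`, character(1), 2L))
      if (anyNA(mz) || anyNA(it))
        stop("malformed MGF peak row near line ", begins[k], " in ", path,
             call. = FALSE)
    } else {
      mz <- it <- numeric(0)
    }
    Spectrum(mz, it, id = if (is.na(title)) paste0("scan", k) else title,
             precursorMz = pepmz, precursorCharge = charge, rt = rt)
  })
}

#' @rdname readMgf
#' @param spectra a list of \linkS4class{Spectrum} objects (or one).
#' @return \code{writeMgf}: the path, invisibly.
#' @export
writeMgf <- function(spectra, path) {
  if (is(spectra, "Spectrum")) spectra <- list(spectra)
  con <- file(path, "w")
  on.exit(close(con))
  for (sp in spectra) {
    writeLines("BEGIN IONS", con)
    writeLines(paste0("TITLE=", sp@id), con)
    if (!is.na(sp@precursorMz))
      writeLines(sprintf("PEPMASS=%.5f", sp@precursorMz), con)
    if (!is.na(sp@precursorCharge))
      writeLines(sprintf("CHARGE=%d+", sp@precursorCharge), con)
    if (!is.na(sp@rt))
      writeLines(sprintf("RTINSECONDS=%.3f", sp@rt * 60), con)
    p <- sp@peaks
    if (nrow(p))
      writeLines(sprintf("%.5f %.6g", p[, 1L], p[, 2L]), con)
    writeLines(c("END IONS", ""), con)
  }
  invisible(path)
}
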