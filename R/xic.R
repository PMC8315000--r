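#' Time-ordered MS1 scan series for one chromatographic run
#'
#' Holds the MS1 peaks of one run on a strictly increasing retention-time
#' grid, together with the run's slot in the kinetics design: its role
#' (\code{"kinetics"}, \code{"control"} for no-proteasome negatives, or
#' \code{"standard"} for synthetic-peptide reference runs), time point in
#' hours, and biological/technical replicate indices.
#'
#' @slot runId run identifier.
#' @slot role one of \code{"kinetics"}, \code{"control"},
#'   \code{"standard"}.
#' @slot timePointH digestion time point in hours (NA for standards).
#' @slot bioRep,techRep replicate indices (NA where not applicable).
#' @slot rt strictly increasing scan retention times, minutes.
#' @slot peaks data.frame \code{scan}, \code{mz}, \code{intensity}; scan
#'   indexes into \code{rt}.
#'
#' @name ChromatogramRun-class
#' @aliases ChromatogramRun-class
#' @exportClass ChromatogramRun
setClass("ChromatogramRun",
  slots = c(runId = "character", role = "character", timePointH = "numeric",
            bioRep = "integer", techRep = "integer", rt = "numeric",
            peaks = "data.frame"))

setValidity("ChromatogramRun", function(object) {
  msg <- character(0)
  if (!object@role %in% c("kinetics", "control", "standard"))
    msg <- c(msg, "role must be kinetics, control or standard")
  if (length(object@rt) > 1L && any(diff(object@rt) <= 0))
    msg <- c(msg, "scan retention times must be strictly increasing")
  p <- object@peaks
  if (!all(c("scan", "mz", "intensity") %in% names(p)))
    msg <- c(msg, "peaks needs columns scan, mz, intensity")
  else if (nrow(p)) {
    if (any(p$scan < 1L | p$scan > length(object@rt)))
      msg <- c(msg, "peak scan index out of range")
    if (any(p$intensity < 0))
      msg <- c(msg, "intensities must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ChromatogramRun
#'
#' @param rt strictly increasing scan retention times (minutes).
#' @param peaks data.frame with columns \code{scan}, \code{mz},
#'   \code{intensity}.
#' @param runId run identifier.
#' @param role \code{"kinetics"}, \code{"control"} or \code{"standard"}.
#' @param timePointH time point in hours (NA for standards).
#' @param bioRep,techRep replicate indices.
#' @return A \linkS4class{ChromatogramRun}.
#' @export
ChromatogramRun <- function(rt, peaks, runId = "run", role = "kinetics",
                            timePointH = NA_real_, bioRep = NA_integer_,
                            techRep = NA_integer_) {
  new("ChromatogramRun", runId = as.character(runId),
      role = as.character(role), timePointH = as.numeric(timePointH),
      bioRep = as.integer(bioRep), techRep = as.integer(techRep),
      rt = as.numeric(rt),
      peaks = as.data.frame(peaks)[, c("scan", "mz", "intensity")])
}

#' @describeIn ChromatogramRun-class run identifier
#' @param x a \code{ChromatogramRun}.
#' @export
runId <- function(x) x@runId

#' @describeIn ChromatogramRun-class design role
#' @export
runRole <- function(x) x@role

#' @describeIn ChromatogramRun-class time point (hours)
#' @export
runTimePoint <- function(x) x@timePointH

#' @describeIn ChromatogramRun-class scan retention-time grid (minutes)
#' @export
scanTimes <- function(x) x@rt

setMethod("show", "ChromatogramRun", function(object) {
  cat("ChromatogramRun '", object@runId, "' [", object@role, "]: ",
      length(object@rt), " scans, ", nrow(object@peaks), " peaks", sep = "")
  if (!is.na(object@timePointH)) cat(", t = ", object@timePointH, " h",
                                     sep = "")
  cat("\n")
})

#' m/z extraction window
#'
#' Inclusive bounds, matching the printed convention of windows such as
#' m/z 421.275-421.875.
#'
#' @param lo,hi window bounds, \code{lo < hi}.
#' @return list of class \code{"MzWindow"}.
#' @export
mzWindow <- function(lo, hi) {
  stopifnot(is.numeric(lo), is.numeric(hi), lo < hi)
  structure(list(lo = lo, hi = hi), class = "MzWindow")
}

#' Extract an ion chromatogram (XIC)
#'
#' Per scan, sums the intensities of all peaks with m/z inside the window
#' (inclusive bounds). Scans with no in-window peaks contribute zero.
#'
#' @param run a \linkS4class{ChromatogramRun}.
#' @param window an \code{\link{mzWindow}}.
#' @return data.frame of class \code{"XicTrace"} with columns \code{rt},
#'   \code{intensity}, one row per scan in scan order.
#' @export
extractXic <- function(run, window) {
  stopifnot(is(run, "ChromatogramRun"), inherits(window, "MzWindow"))
  intensity <- numeric(length(run@rt))
  p <- run@peaks
  sel <- p$mz >= window$lo & p$mz <= window$hi
  if (any(sel)) {
    sums <- tapply(p$intensity[sel], p$scan[sel], sum)
    intensity[as.integer(names(sums))] <- as.numeric(sums)
  }
  structure(data.frame(rt = run@rt, intensity = intensity),
            class = c("XicTrace", "data.frame"))
}

.localMaxima <- function(y) {
  n <- length(y)
  if (n == 0L) return(integer(0))
  left <- c(TRUE, y[-1L] >= y[-n])
  right <- c(y[-n] >= y[-1L], TRUE)
  which(left & right & y > 0)
}

#' Detect a chromatographic peak by reference retention time
#'
#' The apex is the highest local maximum of the trace within
#' \code{rtTol} minutes of the reference RT (measured for the cognate
#' synthetic-standard peptide). Integration bounds are the contiguous scan
#' region around the apex where intensity stays at or above 5% of the apex
#' intensity. The signal-to-noise ratio is apex intensity over the median
#' trace intensity outside the bounds (floored at machine epsilon); the
#' peak is called present iff an apex exists, its above-threshold region
#' spans at least \code{minWidth} scans (an isolated one-scan spike is
#' noise, not a chromatographic peak), and snr >= \code{snrMin}.
#' Absent calls carry area 0 by contract.
#'
#' @param trace an \code{\link{extractXic}} trace.
#' @param refRt reference retention time, minutes.
#' @param rtTol RT matching tolerance, minutes (default 0.5).
#' @param snrMin minimum signal-to-noise ratio for a presence call
#'   (default 3).
#' @param boundFraction fraction of apex intensity defining the
#'   integration bounds (default 0.05).
#' @param minWidth minimum number of scans the above-threshold region must
#'   span (default 3).
#' @return list of class \code{"PeakCall"}: \code{present}, \code{apexRt},
#'   \code{apexIdx}, \code{snr}, \code{loIdx}, \code{hiIdx}, \code{loRt},
#'   \code{hiRt}, \code{area} (0 until integrated).
#' @export
detectPeak <- function(trace, refRt, rtTol = 0.5, snrMin = 3,
                       boundFraction = 0.05, minWidth = 3L) {
  stopifnot(rtTol > 0, snrMin > 0, minWidth >= 1L)
  y <- trace$intensity
  rt <- trace$rt
  absent <- structure(list(present = FALSE, apexRt = NA_real_,
                           apexIdx = NA_integer_, snr = NA_real_,
                           loIdx = NA_integer_, hiIdx = NA_integer_,
                           loRt = NA_real_, hiRt = NA_real_, area = 0),
                      class = "PeakCall")
  cand <- .localMaxima(y)
  cand <- cand[abs(rt[cand] - refRt) <= rtTol]
  if (!length(cand)) return(absent)
  apex <- cand[which.max(y[cand])]
  thr <- boundFraction * y[apex]
  lo <- apex
  while (lo > 1L && y[lo - 1L] >= thr) lo <- lo - 1L
  hi <- apex
  while (hi < length(y) && y[hi + 1L] >= thr) hi <- hi + 1L
  if (hi - lo + 1L < minWidth) return(absent)
  outside <- y[-(lo:hi)]
  noise <- if (length(outside)) max(stats::median(outside),
                                    .Machine$double.eps)
           else .Machine$double.eps
  snr <- y[apex] / noise
  if (snr < snrMin) return(absent)
  structure(list(present = TRUE, apexRt = rt[apex], apexIdx = apex,
                 snr = snr, loIdx = lo, hiIdx = hi, loRt = rt[lo],
                 hiRt = rt[hi], threshold = thr, area = 0),
            class = "PeakCall")
}

#' Integrate the area under a detected peak
#'
#' Trapezoidal integral of the trace between the call's integration bounds
#' against a zero baseline. The exact bound positions are obtained by
#' linear interpolation to the point where the trace crosses the bound
#' threshold (5% of apex by default), so the integral covers the full
#' above-threshold region rather than stopping at the last grid point.
#' Absent calls integrate to 0 by contract.
#'
#' @param trace an \code{\link{extractXic}} trace.
#' @param call a \code{\link{detectPeak}} call.
#' @return Area in intensity x minutes.
#' @export
integrateArea <- function(trace, call) {
  stopifnot(inherits(call, "PeakCall"))
  if (!isTRUE(call$present)) return(0)
  ix <- call$loIdx:call$hiIdx
  rt <- trace$rt[ix]
  y <- trace$intensity[ix]
  thr <- call$threshold
  # extend each side to the interpolated threshold crossing, if any
  lo <- call$loIdx; hi <- call$hiIdx
  yAll <- trace$intensity; rtAll <- trace$rt
  if (lo > 1L && yAll[lo] > thr && yAll[lo - 1L] < yAll[lo]) {
    f <- (yAll[lo] - thr) / (yAll[lo] - yAll[lo - 1L])
    rt <- c(rtAll[lo] - f * (rtAll[lo] - rtAll[lo - 1L]), rt)
    y <- c(thr, y)
  }
  if (hi < length(yAll) && yAll[hi] > thr && yAll[hi + 1L] < yAll[hi]) {
    f <- (yAll[hi] - thr) / (yAll[hi] - yAll[hi + 1L])
    rt <- c(rt, rtAll[hi] + f * (rtAll[hi + 1L] - rtAll[hi]))
    y <- c(y, thr)
  }
  if (length(rt) < 2L) return(0)
  pracma::trapz(rt, y)
}

#' Assemble a digestion-kinetics series from chromatogram runs
#'
#' For each kinetics run: extract the XIC over the window, detect the peak
#' at the reference RT, and integrate its area (0 when absent). Technical
#' replicates of the same biological replicate and time point are averaged
#' (mean); biological replicates are reported separately.
#'
#' @param runs list of \linkS4class{ChromatogramRun} objects; only
#'   \code{role == "kinetics"} runs enter the series.
#' @param window an \code{\link{mzWindow}}.
#' @param refRt reference retention time, minutes.
#' @param rtTol,snrMin passed to \code{\link{detectPeak}}.
#' @param label peptide label attached to the result.
#' @return data.frame of class \code{"KineticsSeries"} with columns
#'   \code{bio}, \code{time_point_h}, \code{area}, \code{n_tech},
#'   \code{n_present}; attribute \code{"label"}.
#' @export
kineticsSeries <- function(runs, window, refRt, rtTol = 0.5, snrMin = 3,
                           label = "peptide") {
  runs <- Filter(function(r) runRole(r) == "kinetics", runs)
  if (!length(runs))
    stop("no kinetics runs supplied", call. = FALSE)
  key <- vapply(runs, function(r)
    paste(r@bioRep, r@techRep, r@timePointH, sep = "|"), character(1))
  if (anyDuplicated(key))
    stop("duplicate (bio, tech, time) run labels in the design",
         call. = FALSE)
  perRun <- lapply(runs, function(r) {
    trace <- extractXic(r, window)
    call <- detectPeak(trace, refRt, rtTol, snrMin)
    data.frame(bio = r@bioRep, tech = r@techRep, time_point_h = r@timePointH,
               area = integrateArea(trace, call),
               present = call$present)
  })
  perRun <- do.call(rbind, perRun)
  agg <- do.call(rbind, lapply(
    split(perRun, list(perRun$bio, perRun$time_point_h), drop = TRUE),
    function(d) data.frame(bio = d$bio[1L],
                           time_point_h = d$time_point_h[1L],
                           area = mean(d$area), n_tech = nrow(d),
                           n_present = sum(d$present))))
  agg <- agg[order(agg$bio, agg$time_point_h), , drop = FALSE]
  rownames(agg) <- NULL
  structure(agg, class = c("KineticsSeries", "data.frame"), label = label)
}

# ---- scans CSV I/O ---------------------------------------------------------

#' Read and write MS1 scan series as CSV
#'
#' The CSV dialect has mandatory columns \code{run_id}, \code{rt_min},
#' \code{mz}, \code{intensity} and optional design columns \code{role},
#' \code{time_point_h}, \code{bio}, \code{tech} (constant within a run).
#' Scans are reconstructed from the distinct \code{rt_min} values of each
#' run. Empty scans (no peaks) use \code{mz = NA} rows to keep the grid.
#'
#' @param path CSV file path.
#' @return \code{readScansCsv}: a list of \linkS4class{ChromatogramRun}.
#' @export
readScansCsv <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("run_id", "rt_min", "mz", "intensity")
  missing <- setdiff(need, names(d))
  if (length(missing))
    stop("scans CSV ", path, " lacks columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  lapply(split(d, d$run_id), function(rd) {
    rt <- sort(unique(rd$rt_min))
    keep <- !is.na(rd$mz)
    peaks <- data.frame(scan = match(rd$rt_min[keep], rt),
                        mz = rd$mz[keep], intensity = rd$intensity[keep])
    meta <- function(col, default) if (col %in% names(rd))
      rd[[col]][1L] else default
    ChromatogramRun(rt, peaks, runId = rd$run_id[1L],
                    role = meta("role", "kinetics"),
                    timePointH = meta("time_point_h", NA_real_),
                    bioRep = meta("bio", NA_integer_),
                    techRep = meta("tech", NA_integer_))
  })
}

#' @rdname readScansCsv
#' @param runs list of \linkS4class{ChromatogramRun} objects (or one).
#' @return \code{writeScansCsv}: the path, invisibly.
#' @export
writeScansCsv <- function(runs, path) {
  if (is(runs, "ChromatogramRun")) runs <- list(runs)
  rows <- lapply(runs, function(r) {
    p <- r@peaks
    # keep empty scans on the grid via NA mz rows
    emptyScans <- setdiff(seq_along(r@rt), unique(p$scan))
    d <- rbind(
      data.frame(scan = p$scan, mz = p$mz, intensity = p$intensity),
      if (length(emptyScans))
        data.frame(scan = emptyScans, mz = NA_real_, intensity = NA_real_))
    d <- d[order(d$scan, d$mz), , drop = FALSE]
    data.frame(run_id = r@runId, rt_min = r@rt[d$scan], mz = d$mz,
               intensity = d$intensity, role = r@role,
               time_point_h = r@timePointH, bio = r@bioRep, tech = r@techRep)
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}
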