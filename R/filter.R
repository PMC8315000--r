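#' Identification filter configuration
#'
#' Thresholds of the peptide-spectrum-match acceptance rule: minimum ion
#' score, maximum q-value, and the two relative delta-score requirements
#' applied to spliced top hits — against the best other spliced hit
#' (default 10%) and against the best non-spliced hit (default 30%). All
#' thresholds are inclusive. The two delta conditions combine with AND by
#' default (the stricter reading); \code{deltaCombine = "or"} accepts a
#' spliced top hit when either condition holds.
#'
#' @param scoreMin minimum ion score (default 20).
#' @param qMax maximum q-value (default 0.05).
#' @param deltaSplicedSpliced minimum percent score gap to the best other
#'   spliced hit (default 10).
#' @param deltaSplicedNonspliced minimum percent score gap to the best
#'   non-spliced hit (default 30).
#' @param deltaCombine \code{"and"} or \code{"or"}.
#' @return A list of class \code{"FilterConfig"}.
#' @export
filterConfig <- function(scoreMin = 20, qMax = 0.05,
                         deltaSplicedSpliced = 10,
                         deltaSplicedNonspliced = 30,
                         deltaCombine = c("and", "or")) {
  deltaCombine <- match.arg(deltaCombine)
  stopifnot(scoreMin >= 0, qMax >= 0, qMax <= 1,
            deltaSplicedSpliced >= 0, deltaSplicedSpliced <= 100,
            deltaSplicedNonspliced >= 0, deltaSplicedNonspliced <= 100)
  structure(list(scoreMin = scoreMin, qMax = qMax,
                 deltaSplicedSpliced = deltaSplicedSpliced,
                 deltaSplicedNonspliced = deltaSplicedNonspliced,
                 deltaCombine = deltaCombine),
            class = "FilterConfig")
}

.HIT_COLUMNS <- c("scan_id", "rank", "sequence", "category", "ion_score",
                  "q_value")

.checkHits <- function(hits) {
  missing <- setdiff(.HIT_COLUMNS, names(hits))
  if (length(missing))
    stop("hit table lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (nrow(hits)) {
    if (any(!hits$category %in% c("spliced", "nonspliced")))
      stop("category must be 'spliced' or 'nonspliced'", call. = FALSE)
    if (any(hits$q_value < 0 | hits$q_value > 1, na.rm = TRUE))
      stop("q_value must lie in [0, 1]", call. = FALSE)
  }
  invisible(hits)
}

# decision for the hits of one scan; returns list(accepted_sequence, reason)
.evaluateScan <- function(h, cfg) {
  topScore <- max(h$ion_score)
  topIdx <- which(h$ion_score == topScore)
  if (length(topIdx) > 1L)
    return(list(sequence = NA_character_, reason = "ambiguous_tie"))
  t <- h[topIdx, ]
  # a non-positive top score with competitors leaves the percentage delta
  # undefined; such scans are rejected outright
  if (topScore <= 0 && nrow(h) > 1L)
    return(list(sequence = NA_character_, reason = "below_score"))
  if (t$ion_score < cfg$scoreMin)
    return(list(sequence = NA_character_, reason = "below_score"))
  if (t$q_value > cfg$qMax)
    return(list(sequence = NA_character_, reason = "above_q"))
  if (t$category == "spliced") {
    others <- h[-topIdx, , drop = FALSE]
    delta <- function(other) 100 * (topScore - other) / topScore
    ssScores <- others$ion_score[others$category == "spliced"]
    snScores <- others$ion_score[others$category == "nonspliced"]
    ssOk <- !length(ssScores) ||
      delta(max(ssScores)) >= cfg$deltaSplicedSpliced
    snOk <- !length(snScores) ||
      delta(max(snScores)) >= cfg$deltaSplicedNonspliced
    pass <- if (cfg$deltaCombine == "and") ssOk && snOk else ssOk || snOk
    if (!pass) {
      reason <- if (!snOk) "delta_sn_fail" else "delta_ss_fail"
      return(list(sequence = NA_character_, reason = reason))
    }
  }
  list(sequence = t$sequence, reason = NA_character_)
}

#' Filter ranked peptide-spectrum hits
#'
#' Applies, per MS2 scan, the identification rule: only the unique
#' top-scoring hit can be accepted (a tied top score rejects the scan as
#' \code{ambiguous_tie}); the top hit must reach the ion-score cutoff and
#' stay under the q-value cutoff; a spliced top hit must additionally beat
#' the best other spliced hit by \code{deltaSplicedSpliced} percent and the
#' best non-spliced hit by \code{deltaSplicedNonspliced} percent of its own
#' score (a missing competitor satisfies its condition vacuously). Lower-
#' ranked hits are never accepted and carry reason \code{not_rank1}.
#'
#' @param hits data.frame with columns \code{scan_id}, \code{rank},
#'   \code{sequence}, \code{category} (\code{"spliced"} or
#'   \code{"nonspliced"}), \code{ion_score}, \code{q_value}.
#' @param cfg a \code{\link{filterConfig}}.
#' @return A list of class \code{"FilterResult"}: \code{scans} (data.frame
#'   \code{scan_id}, \code{accepted_sequence}, \code{reason}; reason is NA
#'   for accepted scans) and \code{hits} (the input with per-hit
#'   \code{accepted} and \code{reason} columns).
#' @export
#' @examples
#' hits <- data.frame(
#'   scan_id = "s1", rank = 1:2, sequence = c("KLVVGAVGV", "KLVVVGAVG"),
#'   category = c("spliced", "nonspliced"), ion_score = c(50, 30),
#'   q_value = 0.01)
#' filterHits(hits)$scans
filterHits <- function(hits, cfg = filterConfig()) {
  .checkHits(hits)
  if (!nrow(hits))
    return(structure(list(
      scans = data.frame(scan_id = character(0),
                         accepted_sequence = character(0),
                         reason = character(0)),
      hits = cbind(hits, accepted = logical(0), reason = character(0))),
      class = "FilterResult"))
  byScan <- split(seq_len(nrow(hits)), hits$scan_id)
  hitAccepted <- rep(FALSE, nrow(hits))
  hitReason <- rep("not_rank1", nrow(hits))
  scanRows <- lapply(names(byScan), function(id) {
    ix <- byScan[[id]]
    dec <- .evaluateScan(hits[ix, , drop = FALSE], cfg)
    topIdx <- ix[which.max(hits$ion_score[ix])]
    if (!is.na(dec$sequence)) {
      hitAccepted[topIdx] <<- TRUE
      hitReason[topIdx] <<- NA_character_
    } else {
      hitReason[topIdx] <<- dec$reason
    }
    data.frame(scan_id = id, accepted_sequence = dec$sequence,
               reason = dec$reason)
  })
  scans <- do.call(rbind, scanRows)
  rownames(scans) <- NULL
  structure(list(scans = scans,
                 hits = cbind(hits, accepted = hitAccepted,
                              reason = hitReason)),
            class = "FilterResult")
}

#' Read a search-hit table; write a filter report
#'
#' \code{readHitTable} reads a CSV with columns \code{scan_id},
#' \code{rank}, \code{sequence}, \code{ion_score}, \code{q_value} and an
#' optional \code{category} column. When \code{category} is absent a
#' substrate must be supplied and categories are filled via
#' \code{\link{classifySequence}} (\code{spliced_only} maps to
#' \code{"spliced"}; \code{nonspliced} and \code{not_producible} map to
#' \code{"nonspliced"}, the latter because a non-producible sequence
#' competes like any non-spliced hit).
#'
#' @param path CSV file path.
#' @param substrate optional \linkS4class{Substrate} used to derive missing
#'   categories.
#' @param cfg an \code{\link{enumerationConfig}} passed to
#'   \code{classifySequence}.
#' @return \code{readHitTable}: the validated hit data.frame.
#' @export
readHitTable <- function(path, substrate = NULL,
                         cfg = enumerationConfig()) {
  hits <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- setdiff(.HIT_COLUMNS, "category")
  missing <- setdiff(required, names(hits))
  if (length(missing))
    stop("hit table ", path, " lacks required columns: ",
         paste(missing, collapse = ", "), call. = FALSE)
  if (!"category" %in% names(hits)) {
    if (is.null(substrate))
      stop("hit table has no category column and no substrate was supplied",
           call. = FALSE)
    hits$category <- vapply(hits$sequence, function(s)
      switch(classifySequence(s, substrate, cfg),
             spliced_only = "spliced", "nonspliced"),
      character(1), USE.NAMES = FALSE)
  }
  hits$scan_id <- as.character(hits$scan_id)
  .checkHits(hits[, .HIT_COLUMNS, drop = FALSE])
  hits
}

#' @rdname readHitTable
#' @param result a \code{\link{filterHits}} result.
#' @return \code{writeFilterReport}: the path, invisibly.
#' @export
writeFilterReport <- function(result, path) {
  stopifnot(inherits(result, "FilterResult"))
  utils::write.csv(result$scans, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Target-decoy q-values (plumbing helper)
#'
#' Standard q-value estimation by decoy counting for fully synthetic runs:
#' at each score threshold the FDR estimate is (number of decoys at or
#' above the threshold) / (number of targets at or above it), and q-values
#' are the monotone minimum of FDR over all thresholds at or below each
#' hit's score. This helper exists so simulated hit tables can carry
#' realistic q-values; real q-values are consumed, not computed, by the
#' filter.
#'
#' @param score numeric scores (higher is better).
#' @param isDecoy logical, TRUE for decoy hits.
#' @return numeric q-value per hit (decoy entries get their threshold's
#'   estimate as well).
#' @export
targetDecoyQValues <- function(score, isDecoy) {
  stopifnot(length(score) == length(isDecoy))
  o <- order(score, decreasing = TRUE)
  dec <- cumsum(isDecoy[o])
  tar <- cumsum(!isDecoy[o])
  fdr <- ifelse(tar > 0, dec / tar, 1)
  q <- rev(cummin(rev(pmin(fdr, 1))))
  out <- numeric(length(score))
  out[o] <- q
  out
}
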