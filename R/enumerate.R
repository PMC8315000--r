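#' Enumeration configuration
#'
#' Settings controlling the candidate-peptidome enumeration: product length
#' bounds, minimum splice-reactant length, whether reverse cis events are
#' generated, and the variable-modification budget used when peptidoforms
#' are expanded.
#'
#' @param minLen,maxLen product length bounds in residues (defaults 5 and
#'   25, bracketing HLA class I relevant lengths).
#' @param minReactantLen minimum length of each splice reactant (default 1).
#' @param allowReverse generate reverse cis-spliced products (default TRUE).
#' @param maxVariableMods maximum number of variable modifications per
#'   peptidoform (default 2).
#' @return A validated list of class \code{"EnumerationConfig"}.
#' @export
enumerationConfig <- function(minLen = 5L, maxLen = 25L,
                              minReactantLen = 1L, allowReverse = TRUE,
                              maxVariableMods = 2L) {
  minLen <- as.integer(minLen); maxLen <- as.integer(maxLen)
  minReactantLen <- as.integer(minReactantLen)
  maxVariableMods <- as.integer(maxVariableMods)
  stopifnot(minLen >= 1L, minLen <= maxLen, minReactantLen >= 1L,
            maxVariableMods >= 0L, is.logical(allowReverse))
  structure(list(minLen = minLen, maxLen = maxLen,
                 minReactantLen = minReactantLen,
                 allowReverse = isTRUE(allowReverse),
                 maxVariableMods = maxVariableMods),
            class = "EnumerationConfig")
}

# ---- origin notation -------------------------------------------------------

#' Parse and format splice-origin notation
#'
#' Origins are written in the field's compact interval notation in protein
#' coordinates: \code{"5-13"} for a non-spliced (contiguous) product,
#' \code{"5-6/8-14"} for a spliced product whose first printed interval is
#' splice reactant 1 (the N-terminal part of the product). The spliced form
#' is classified normal cis (reactant 2 starts at least two residues after
#' reactant 1 ends, i.e. at least one residue is skipped) or reverse cis
#' (reactant 2 lies entirely N-terminal to reactant 1) from the coordinate
#' order; adjacent or overlapping intervals in normal order are rejected
#' because they do not describe a splice event.
#'
#' @param text origin string, \code{"a-b"} or \code{"a-b/c-d"}.
#' @return \code{parseOrigin}: a list with elements \code{kind} (one of
#'   \code{"nonspliced"}, \code{"cis_normal"}, \code{"cis_reverse"}) and the
#'   interval coordinates (\code{start}/\code{end} or \code{r1_start},
#'   \code{r1_end}, \code{r2_start}, \code{r2_end}).
#' @export
#' @examples
#' parseOrigin("5-6/8-14")$kind   # "cis_normal"
#' formatOrigin(parseOrigin("5-13"))
parseOrigin <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  if (grepl("^[0-9]+-[0-9]+$", text)) {
    ab <- as.integer(strsplit(text, "-", fixed = TRUE)[[1L]])
    if (ab[1L] > ab[2L]) stop("malformed origin '", text,
                              "': start > end", call. = FALSE)
    return(list(kind = "nonspliced", start = ab[1L], end = ab[2L]))
  }
  if (grepl("^[0-9]+-[0-9]+/[0-9]+-[0-9]+$", text)) {
    parts <- strsplit(text, "/", fixed = TRUE)[[1L]]
    r1 <- as.integer(strsplit(parts[1L], "-", fixed = TRUE)[[1L]])
    r2 <- as.integer(strsplit(parts[2L], "-", fixed = TRUE)[[1L]])
    if (r1[1L] > r1[2L] || r2[1L] > r2[2L])
      stop("malformed origin '", text, "': start > end", call. = FALSE)
    kind <- if (r2[1L] >= r1[2L] + 2L) "cis_normal"
            else if (r2[2L] <= r1[1L] - 1L) "cis_reverse"
            else stop("origin '", text,
                      "' is not a valid splice event (intervals touch or ",
                      "overlap in normal order)", call. = FALSE)
    return(list(kind = kind, r1_start = r1[1L], r1_end = r1[2L],
                r2_start = r2[1L], r2_end = r2[2L]))
  }
  stop("malformed origin notation: '", text, "'", call. = FALSE)
}

#' @rdname parseOrigin
#' @param origin a parsed origin list as returned by \code{parseOrigin}.
#' @return \code{formatOrigin}: the notation string; round-trip stable.
#' @export
formatOrigin <- function(origin) {
  if (origin$kind == "nonspliced")
    sprintf("%d-%d", origin$start, origin$end)
  else
    sprintf("%d-%d/%d-%d", origin$r1_start, origin$r1_end,
            origin$r2_start, origin$r2_end)
}

# ---- enumeration -----------------------------------------------------------

.collapseEvents <- function(events) {
  if (nrow(events) == 0L)
    return(data.frame(sequence = character(0), category = character(0),
                      origins = character(0), length = integer(0),
                      n_origins = integer(0)))
  events <- unique(events)
  key <- events$sequence
  origins <- vapply(split(events$origin, key), function(o)
    paste(sort(unique(o)), collapse = ";"), character(1))
  cat_by_seq <- vapply(split(events$kind, key), function(k)
    if (any(k == "nonspliced")) "nonspliced" else "spliced", character(1))
  seqs <- names(origins)
  out <- data.frame(sequence = seqs, category = cat_by_seq[seqs],
                    origins = origins[seqs], length = nchar(seqs),
                    n_origins = lengths(strsplit(origins[seqs], ";",
                                                 fixed = TRUE)),
                    row.names = NULL)
  out[order(out$length, out$sequence), , drop = FALSE]
}

#' Enumerate non-spliced peptide products
#'
#' All contiguous substrings of the substrate whose length falls within the
#' configured bounds, reported in protein coordinates. Sequence-identical
#' products arising from different positions are merged and carry all
#' generating origins.
#'
#' @param substrate a \linkS4class{Substrate}.
#' @param cfg an \code{\link{enumerationConfig}}.
#' @param collapse if TRUE (default) merge events by sequence into products;
#'   if FALSE return one row per generating event.
#' @return A data.frame. Collapsed: columns \code{sequence},
#'   \code{category}, \code{origins} (semicolon-joined notation),
#'   \code{length}, \code{n_origins}. Uncollapsed: one row per event with
#'   \code{sequence}, \code{kind}, \code{origin}.
#' @export
#' @examples
#' kras <- Substrate("TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT", offset = 2)
#' db <- enumerateNonspliced(kras, enumerationConfig(9, 9))
#' db[db$sequence == "KLVVVGAVG", ]
enumerateNonspliced <- function(substrate, cfg = enumerationConfig(),
                                collapse = TRUE) {
  stopifnot(is(substrate, "Substrate"), inherits(cfg, "EnumerationConfig"))
  s <- substrateSeq(substrate); n <- nchar(s)
  lens <- seq.int(cfg$minLen, min(cfg$maxLen, n))
  if (n < cfg$minLen) lens <- integer(0)
  rows <- lapply(lens, function(L) {
    starts <- seq_len(n - L + 1L)
    data.frame(sequence = substring(s, starts, starts + L - 1L),
               kind = "nonspliced",
               start = .toProtein(substrate, starts),
               end = .toProtein(substrate, starts + L - 1L))
  })
  events <- if (length(rows)) do.call(rbind, rows) else
    data.frame(sequence = character(0), kind = character(0),
               start = integer(0), end = integer(0))
  events$origin <- if (nrow(events))
    sprintf("%d-%d", events$start, events$end) else character(0)
  if (!collapse) return(events[, c("sequence", "kind", "origin")])
  .collapseEvents(events[, c("sequence", "kind", "origin")])
}

#' Enumerate cis-spliced peptide products
#'
#' All products formed by ligating two splice reactants cut from a single
#' substrate molecule. In normal-order cis splicing reactant 2 lies
#' C-terminal to reactant 1 with at least one intervening (skipped) residue;
#' in reverse-order cis splicing reactant 2 lies entirely N-terminal to
#' reactant 1 (adjacent allowed, overlap forbidden, since one molecule
#' cannot contribute a residue twice). Reactant 1 is always the N-terminal
#' part of the product. Sequence-identical products are merged with all
#' generating origins retained.
#'
#' @inheritParams enumerateNonspliced
#' @return As \code{\link{enumerateNonspliced}}; event \code{kind} is
#'   \code{"cis_normal"} or \code{"cis_reverse"}.
#' @export
#' @examples
#' kras <- Substrate("TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT", offset = 2)
#' db <- enumerateCisSpliced(kras, enumerationConfig(9, 9))
#' db[db$sequence == "KLVVGAVGV", "origins"]
enumerateCisSpliced <- function(substrate, cfg = enumerationConfig(),
                                collapse = TRUE) {
  stopifnot(is(substrate, "Substrate"), inherits(cfg, "EnumerationConfig"))
  s <- substrateSeq(substrate); n <- nchar(s)
  empty <- data.frame(sequence = character(0), kind = character(0),
                      origin = character(0))
  maxReact <- cfg$maxLen - cfg$minReactantLen
  if (n < 2L * cfg$minReactantLen || maxReact < cfg$minReactantLen)
    return(if (collapse) .collapseEvents(empty) else empty)

  # all intervals usable as a reactant
  iv <- expand.grid(i = seq_len(n), j = seq_len(n))
  iv <- iv[iv$j >= iv$i, , drop = FALSE]
  len <- iv$j - iv$i + 1L
  keep <- len >= cfg$minReactantLen & len <= maxReact
  iv <- iv[keep, , drop = FALSE]
  m <- nrow(iv)
  if (m == 0L) return(if (collapse) .collapseEvents(empty) else empty)

  a <- iv[rep(seq_len(m), each = m), , drop = FALSE]    # reactant 1
  b <- iv[rep(seq_len(m), times = m), , drop = FALSE]   # reactant 2
  total <- (a$j - a$i + 1L) + (b$j - b$i + 1L)
  inBounds <- total >= cfg$minLen & total <= cfg$maxLen
  normal <- inBounds & (b$i >= a$j + 2L)
  reverse <- if (cfg$allowReverse) inBounds & (b$j <= a$i - 1L) else
    rep(FALSE, length(inBounds))
  sel <- normal | reverse
  if (!any(sel)) return(if (collapse) .collapseEvents(empty) else empty)
  a <- a[sel, , drop = FALSE]; b <- b[sel, , drop = FALSE]
  kind <- ifelse(normal[sel], "cis_normal", "cis_reverse")
  events <- data.frame(
    sequence = paste0(substring(s, a$i, a$j), substring(s, b$i, b$j)),
    kind = kind,
    origin = sprintf("%d-%d/%d-%d",
                     .toProtein(substrate, a$i), .toProtein(substrate, a$j),
                     .toProtein(substrate, b$i), .toProtein(substrate, b$j)))
  if (!collapse) return(events)
  .collapseEvents(events)
}

#' Enumerate the full candidate peptidome (the customized database)
#'
#' Union of non-spliced and cis-spliced products. A sequence producible
#' both ways is categorised \code{"nonspliced"} (the substring reading takes
#' precedence) and keeps the origins of every generating event.
#'
#' @inheritParams enumerateNonspliced
#' @return Collapsed product data.frame as in
#'   \code{\link{enumerateNonspliced}}.
#' @export
enumerateProducts <- function(substrate, cfg = enumerationConfig()) {
  ns <- enumerateNonspliced(substrate, cfg, collapse = FALSE)
  cs <- enumerateCisSpliced(substrate, cfg, collapse = FALSE)
  .collapseEvents(rbind(ns, cs))
}

# all (possibly overlapping) start positions of pat in s
.occurrences <- function(s, pat) {
  n <- nchar(s); m <- nchar(pat)
  if (m > n) return(integer(0))
  starts <- seq_len(n - m + 1L)
  starts[substring(s, starts, starts + m - 1L) == pat]
}

#' Classify a peptide sequence against a substrate
#'
#' A sequence is \code{"nonspliced"} if it occurs as a contiguous substring
#' of the substrate, \code{"spliced_only"} if it is not a substring but can
#' be generated by at least one cis-splicing event under the configuration
#' (minimum reactant length, reverse allowed or not; product length bounds
#' are not applied here), and \code{"not_producible"} otherwise.
#'
#' @param sequence peptide string.
#' @inheritParams enumerateNonspliced
#' @return One of \code{"nonspliced"}, \code{"spliced_only"},
#'   \code{"not_producible"}.
#' @export
#' @examples
#' kras <- Substrate("TEYKLVVVGAVGVGKSALTIQLIQNHFVDEYDPT", offset = 2)
#' classifySequence("KLVVGAVGV", kras)   # spliced_only
#' classifySequence("KLVVVGAVG", kras)   # nonspliced
classifySequence <- function(sequence, substrate,
                             cfg = enumerationConfig()) {
  .checkAlphabet(sequence)
  s <- substrateSeq(substrate)
  if (length(.occurrences(s, sequence)) > 0L) return("nonspliced")
  L <- nchar(sequence)
  if (L >= 2L * cfg$minReactantLen) {
    for (k in seq.int(cfg$minReactantLen, L - cfg$minReactantLen)) {
      p1 <- substr(sequence, 1L, k)
      p2 <- substr(sequence, k + 1L, L)
      occ1 <- .occurrences(s, p1)
      if (!length(occ1)) next
      occ2 <- .occurrences(s, p2)
      if (!length(occ2)) next
      for (i1 in occ1) {
        j1 <- i1 + k - 1L
        for (i2 in occ2) {
          j2 <- i2 + (L - k) - 1L
          if (i2 >= j1 + 2L) return("spliced_only")                 # normal
          if (cfg$allowReverse && j2 <= i1 - 1L) return("spliced_only")
        }
      }
    }
  }
  "not_producible"
}

# ---- peptidoform expansion -------------------------------------------------

#' Expand variable-modification peptidoforms
#'
#' Enumerates all peptidoforms of a sequence carrying up to
#' \code{maxVariableMods} variable modifications: oxidation on M
#' (+15.994915 Da) and deamidation on N or Q (+0.984016 Da). The unmodified
#' form is always included.
#'
#' @param sequence peptide string.
#' @param maxVariableMods modification budget; defaults to the value in
#'   \code{cfg}.
#' @param cfg an \code{\link{enumerationConfig}} supplying the default
#'   budget.
#' @return A list of peptidoforms; each is a list with \code{sequence} and
#'   \code{mods}, a data.frame with columns \code{pos}, \code{name},
#'   \code{delta} (zero rows for the unmodified form).
#' @export
#' @examples
#' length(expandModifications("NQM", maxVariableMods = 3))  # 8
#' length(expandModifications("KLVVGAVGV"))                 # 1
expandModifications <- function(sequence, maxVariableMods = cfg$maxVariableMods,
                                cfg = enumerationConfig()) {
  letters <- .checkAlphabet(sequence)
  stopifnot(maxVariableMods >= 0L)
  sites <- data.frame(pos = integer(0), name = character(0),
                      delta = numeric(0))
  for (p in seq_along(letters)) {
    if (letters[p] == "M")
      sites <- rbind(sites, data.frame(pos = p, name = "oxidation",
                                       delta = .MOD_OXIDATION))
    else if (letters[p] %in% c("N", "Q"))
      sites <- rbind(sites, data.frame(pos = p, name = "deamidation",
                                       delta = .MOD_DEAMIDATION))
  }
  forms <- list(list(sequence = sequence, mods = sites[0L, , drop = FALSE]))
  nmax <- min(nrow(sites), maxVariableMods)
  if (nmax >= 1L) {
    for (sz in seq_len(nmax)) {
      combos <- utils::combn(nrow(sites), sz, simplify = FALSE)
      forms <- c(forms, lapply(combos, function(ix)
        list(sequence = sequence, mods = sites[ix, , drop = FALSE])))
    }
  }
  forms
}

# ---- database export -------------------------------------------------------

#' Write an enumeration table to CSV or FASTA
#'
#' \code{writeEnumerationCsv} writes the collapsed product table with
#' columns \code{sequence}, \code{category}, \code{origins}, \code{length}.
#' \code{writeEnumerationFasta} writes the candidate sequences as a FASTA
#' "customized database", headers \code{<category>|<origins>}.
#'
#' @param products collapsed product data.frame.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
writeEnumerationCsv <- function(products, path) {
  utils::write.csv(products[, c("sequence", "category", "origins", "length")],
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname writeEnumerationCsv
#' @export
writeEnumerationFasta <- function(products, path) {
  set <- Biostrings::AAStringSet(products$sequence)
  names(set) <- paste(products$category, products$origins, sep = "|")
  Biostrings::writeXStringSet(set, path)
  invisible(path)
}
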