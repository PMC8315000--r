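# Independent brute-force oracles used to cross-check the optimized
# implementations. These deliberately share no code with the package paths
# they verify.

# all cis-splice events of `seq` by a plain double loop over every ordered
# pair of intervals; returns a data.frame(sequence, kind, origin)
bruteCisEvents <- function(seq, offset = 1L, minLen, maxLen,
                           minReactant = 1L, allowReverse = TRUE) {
  n <- nchar(seq)
  iv <- list()
  for (i in seq_len(n))
    for (j in i:n)
      if (j - i + 1L >= minReactant) iv[[length(iv) + 1L]] <- c(i, j)
  rows <- list()
  for (a in iv) {
    for (b in iv) {
      total <- (a[2L] - a[1L] + 1L) + (b[2L] - b[1L] + 1L)
      if (total < minLen || total > maxLen) next
      isNormal <- b[1L] >= a[2L] + 2L
      isReverse <- allowReverse && b[2L] <= a[1L] - 1L
      if (!isNormal && !isReverse) next
      rows[[length(rows) + 1L]] <- data.frame(
        sequence = paste0(substr(seq, a[1L], a[2L]),
                          substr(seq, b[1L], b[2L])),
        kind = if (isNormal) "cis_normal" else "cis_reverse",
        origin = sprintf("%d-%d/%d-%d",
                         a[1L] + offset - 1L, a[2L] + offset - 1L,
                         b[1L] + offset - 1L, b[2L] + offset - 1L))
    }
  }
  if (!length(rows))
    return(data.frame(sequence = character(0), kind = character(0),
                      origin = character(0)))
  unique(do.call(rbind, rows))
}

# residue composition (sorted letters) of every prefix and suffix; used as
# the mass-free oracle for the shared/diagnostic fragment partition of
# isobaric sequence isomers
fragmentCompositions <- function(seq) {
  n <- nchar(seq)
  letters <- strsplit(seq, "")[[1L]]
  comp <- function(x) paste(sort(x), collapse = "")
  list(
    prefix = vapply(seq_len(n - 1L), function(i)
      comp(letters[1:i]), character(1)),
    suffix = vapply(seq_len(n - 1L), function(i)
      comp(letters[(n - i + 1L):n]), character(1)))
}

randomPeptide <- function(len, alphabet = names(residueMasses())) {
  paste(sample(alphabet, len, replace = TRUE), collapse = "")
}

# a clean simulated spectrum of every b/y ion of a peptide, optional ppm
# jitter, no noise peaks
cleanSpectrum <- function(sequence, fragCfg, jitterPpm = 0, seed = NULL) {
  fr <- theoreticalFragments(sequence, cfg = fragCfg)
  mz <- fr$mz
  if (jitterPpm > 0) {
    if (!is.null(seed)) set.seed(seed)
    mz <- mz * (1 + rnorm(length(mz), 0, jitterPpm) * 1e-6)
  }
  Spectrum(mz, rep(100, length(mz)), id = paste0("clean_", sequence))
}

# synthetic Gaussian XIC trace with a known analytic area
gaussianTrace <- function(area, apexRt, sigma = 0.1, spacing = 0.02,
                          rtRange = c(5, 15), noise = 0) {
  rt <- seq(rtRange[1], rtRange[2], by = spacing)
  y <- area * dnorm(rt, apexRt, sigma)
  if (noise > 0) y <- y + runif(length(rt), 0, noise)
  structure(data.frame(rt = rt, intensity = y),
            class = c("XicTrace", "data.frame"))
}
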