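# Independent reference implementations used to cross-check the package:
# exhaustive window searches for both trimming profiles and a pure-R
# affine-gap (Gotoh) local aligner with the same documented tie-breaks.

# Longest window [s, e] such that every full-size sub-window inside has
# mean QV >= cutoff (windows shorter than the sub-window size are judged
# by their own mean).  Ties on length -> earliest start.  Returns
# c(start, end); c(1, 0) when nothing qualifies.
oracleTrimSliding <- function(q, w, cutoff) {
  n <- length(q)
  best <- c(1L, 0L)
  if (n == 0L) return(best)
  wm <- if (n >= w)
    vapply(seq_len(n - w + 1L), function(i) mean(q[i:(i + w - 1L)]),
           numeric(1))
  else numeric(0)
  for (s in seq_len(n)) {
    if (n - s + 1L >= w) {
      v <- cummin(wm[s:(n - w + 1L)])
      bad <- which(v < cutoff)
      maxE <- if (!length(bad)) n
              else if (bad[1L] == 1L) NA_integer_
              else s + w - 2L + bad[1L] - 1L
      if (!is.na(maxE) && maxE - s > best[2L] - best[1L])
        best <- c(s, maxE)
    }
    for (len in seq_len(min(w - 1L, n - s + 1L))) {
      e <- s + len - 1L
      if (mean(q[s:e]) >= cutoff && e - s > best[2L] - best[1L])
        best <- c(s, e)
    }
  }
  best
}

# Longest window with (low-QV fraction < lowFrac) and (undetermined
# fraction <= ambFrac); incremental scalar counters over every (s, e).
oracleTrimManual <- function(q, chars, lowTh = 30, lowFrac = 0.15,
                             ambFrac = 0.10) {
  n <- length(q)
  best <- c(1L, 0L)
  if (n == 0L) return(best)
  low <- q <= lowTh
  amb <- !(chars %in% c("A", "C", "G", "T"))
  for (s in seq_len(n)) {
    nLow <- 0L; nAmb <- 0L
    for (e in s:n) {
      len <- e - s + 1L
      nLow <- nLow + (if (low[e]) 1L else 0L)
      nAmb <- nAmb + (if (amb[e]) 1L else 0L)
      if (nLow < lowFrac * len && nAmb <= ambFrac * len &&
          len > best[2L] - best[1L] + 1L)
        best <- c(s, e)
    }
  }
  best
}

# Gotoh local alignment in plain R, following the same deterministic
# conventions documented for localAlign(): gap of length L costs
# go + L * ge; tie preference diagonal > E (gap in query) > F > stop;
# within E/F, opening from H preferred over extending; traceback starts
# at the best cell with the smallest query, then subject, index.
oracleLocalAlign <- function(a, b, match = 1, mismatch = -2,
                             go = 5, ge = 2) {
  A <- strsplit(a, "")[[1L]]; B <- strsplit(b, "")[[1L]]
  n <- length(A); m <- length(B); NEG <- -1e18
  H <- matrix(0, n + 1L, m + 1L)
  E <- matrix(NEG, n + 1L, m + 1L); F <- matrix(NEG, n + 1L, m + 1L)
  cH <- matrix(0L, n + 1L, m + 1L)
  cE <- matrix(0L, n + 1L, m + 1L); cF <- matrix(0L, n + 1L, m + 1L)
  best <- 0; bi <- 0L; bj <- 0L
  for (i in 2L:(n + 1L)) for (j in 2L:(m + 1L)) {
    eo <- H[i, j - 1L] - go - ge; ee <- E[i, j - 1L] - ge
    if (eo >= ee) { E[i, j] <- eo; cE[i, j] <- 1L }
    else          { E[i, j] <- ee; cE[i, j] <- 2L }
    fo <- H[i - 1L, j] - go - ge; fe <- F[i - 1L, j] - ge
    if (fo >= fe) { F[i, j] <- fo; cF[i, j] <- 1L }
    else          { F[i, j] <- fe; cF[i, j] <- 2L }
    dg <- H[i - 1L, j - 1L] +
      (if (A[i - 1L] == B[j - 1L]) match else mismatch)
    h <- 0; ch <- 0L
    if (dg >= h) { h <- dg; ch <- 1L }
    if (E[i, j] > h) { h <- E[i, j]; ch <- 2L }
    if (F[i, j] > h) { h <- F[i, j]; ch <- 3L }
    if (h <= 0) { h <- 0; ch <- 0L }
    H[i, j] <- h; cH[i, j] <- ch
    if (h > best) { best <- h; bi <- i; bj <- j }
  }
  if (best <= 0)
    return(list(score = 0, matches = 0L, alignedLength = 0L,
                queryStart = NA_integer_, queryEnd = NA_integer_))
  i <- bi; j <- bj; matches <- 0L; cols <- 0L; state <- "H"
  repeat {
    if (state == "H") {
      if (H[i, j] <= 0 || cH[i, j] == 0L) break
      ch <- cH[i, j]
      if (ch == 1L) {
        cols <- cols + 1L
        if (A[i - 1L] == B[j - 1L]) matches <- matches + 1L
        i <- i - 1L; j <- j - 1L
      } else if (ch == 2L) state <- "E" else state <- "F"
    } else if (state == "E") {
      ch <- cE[i, j]; cols <- cols + 1L; j <- j - 1L
      if (ch == 1L) state <- "H"
    } else {
      ch <- cF[i, j]; cols <- cols + 1L; i <- i - 1L
      if (ch == 1L) state <- "H"
    }
  }
  list(score = best, matches = matches, alignedLength = cols,
       queryStart = i, queryEnd = bi - 1L)
}
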