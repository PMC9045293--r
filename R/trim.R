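# Quality trimming: automated sliding-window profile and the stricter
# manual-review profile, plus read-level QC and mixed-base calling.

#' Trimming parameter sets
#'
#' Two named profiles are provided.  The \code{"automated"} profile trims by
#' mean quality over a sliding window (mean QV >= 40 over 10 bp, minimum
#' clear length 20).  The \code{"manual"} profile mimics interactive
#' chromatogram review software: at most 15\% of retained bases may have
#' QV <= 30, at most 10\% may be undetermined, minimum clear length 50,
#' and at most 20 mixed (ambiguous) basecalls.  Both use a secondary-peak
#' signal-to-noise ratio of 0.33 for mixed-base calling.
#'
#' @param profile \code{"automated"} or \code{"manual"}.
#' @param windowQvCutoff Mean-QV threshold for the sliding window.
#' @param windowSize Sliding-window width in bases.
#' @param minClearLength Minimum retained length for the window to pass.
#' @param signalToNoise Secondary/primary peak ratio at or above which a
#'   basecall becomes an ambiguity code.
#' @param maxUndeterminedFraction Maximum fraction of non-ACGT bases in the
#'   retained window (manual profile).
#' @param lowQvFractionCutoff Maximum fraction of bases with
#'   QV <= \code{lowQvThreshold} in the retained window, exclusive
#'   (manual profile).
#' @param lowQvThreshold QV at or below which a base counts as low quality.
#' @param maxMixedBases Maximum mixed (non-ACGT, non-N) basecalls tolerated
#'   in a passing window (manual profile).
#' @param readMeanQvCutoff Mean trimmed QV a read must exceed to pass QC.
#' @return A list of class \code{"TrimParams"}.
#' @export
trimParams <- function(profile = c("automated", "manual"),
                       windowQvCutoff = 40,
                       windowSize = 10L,
                       minClearLength = if (profile[1L] == "manual") 50L
                                        else 20L,
                       signalToNoise = 0.33,
                       maxUndeterminedFraction = 0.10,
                       lowQvFractionCutoff = 0.15,
                       lowQvThreshold = 30,
                       maxMixedBases = 20L,
                       readMeanQvCutoff = 30) {
  profile <- match.arg(profile)
  p <- list(profile = profile,
            windowQvCutoff = windowQvCutoff,
            windowSize = as.integer(windowSize),
            minClearLength = as.integer(minClearLength),
            signalToNoise = signalToNoise,
            maxUndeterminedFraction = maxUndeterminedFraction,
            lowQvFractionCutoff = lowQvFractionCutoff,
            lowQvThreshold = lowQvThreshold,
            maxMixedBases = as.integer(maxMixedBases),
            readMeanQvCutoff = readMeanQvCutoff)
  stopifnot(p$windowSize >= 1L, p$windowQvCutoff >= 0,
            p$minClearLength >= 0L,
            p$signalToNoise > 0, p$signalToNoise <= 1,
            p$maxUndeterminedFraction >= 0, p$maxUndeterminedFraction <= 1,
            p$lowQvFractionCutoff >= 0, p$lowQvFractionCutoff <= 1)
  class(p) <- "TrimParams"
  p
}

.newTrimWindow <- function(q, ambFlags, start, end, minClear) {
  if (end < start)
    return(new("TrimWindow", start = 1L, end = 0L, passed = FALSE,
               reason = sprintf("no window met the quality criteria; clear length 0 < min_clear_length %d",
                                minClear),
               meanQV = NaN, nAmbiguous = 0L))
  len <- end - start + 1L
  passed <- len >= minClear
  new("TrimWindow", start = as.integer(start), end = as.integer(end),
      passed = passed,
      reason = if (passed) "" else
        sprintf("clear length %d < min_clear_length %d", len, minClear),
      meanQV = mean(q[start:end]),
      nAmbiguous = sum(ambFlags[start:end]))
}

#' Sliding-window quality trimming (automated profile)
#'
#' Returns the longest contiguous stretch of the read in which every
#' full-size sliding window has mean QV at or above the cutoff.  Candidate
#' stretches shorter than the window size (including whole reads shorter
#' than one window) are judged by the mean over their available bases.
#' Ties on length are broken by the earliest start.
#'
#' @param read A \linkS4class{SangerRead}.
#' @param params A \code{\link{trimParams}} object.
#' @return A \linkS4class{TrimWindow}; \code{passed} is TRUE when the
#'   retained stretch reaches \code{minClearLength}.
#' @export
trimSlidingWindow <- function(read, params = trimParams("automated")) {
  q <- qualities(read)
  n <- length(q)
  amb <- !(.splitBases(bases(read)) %in% c("A", "C", "G", "T"))
  w <- params$windowSize
  cutoff <- params$windowQvCutoff
  if (n == 0L)
    return(.newTrimWindow(q, amb, 1L, 0L, params$minClearLength))

  cs <- cumsum(as.numeric(q))
  best <- c(1L, 0L)                     # start, end (empty)
  if (n >= w) {
    # sums of each full window; runs of passing windows give the candidates
    winSum <- cs[w:n] - c(0, cs)[1:(n - w + 1L)]
    ok <- winSum >= cutoff * w
    r <- rle(ok)
    pos <- cumsum(c(1L, r$lengths))
    for (j in seq_along(r$values)) {
      if (!r$values[j]) next
      s <- pos[j]
      e <- pos[j + 1L] - 1L + w - 1L    # window start of last ok + w - 1
      if ((e - s) > (best[2L] - best[1L])) best <- c(s, e)
    }
  }
  maxShort <- min(w, n) - 1L + (n < w)
  if (best[2L] < best[1L] && maxShort >= 1L) {
    # no full-size window passes (or the read is shorter than one window):
    # take the longest sub-window-size stretch whose mean clears the cutoff
    for (len in seq(maxShort, 1L)) {
      sums <- cs[len:n] - c(0, cs)[1:(n - len + 1L)]
      hit <- which(sums >= cutoff * len)
      if (length(hit)) { best <- c(hit[1L], hit[1L] + len - 1L); break }
    }
  }
  .newTrimWindow(q, amb, best[1L], best[2L], params$minClearLength)
}

#' Manual-profile quality trimming
#'
#' Returns the longest contiguous window in which the fraction of bases
#' with QV <= \code{lowQvThreshold} stays strictly below
#' \code{lowQvFractionCutoff} and the fraction of undetermined (non-ACGT)
#' bases stays at or below \code{maxUndeterminedFraction}.  The window
#' passes when it additionally reaches \code{minClearLength} and contains
#' at most \code{maxMixedBases} mixed basecalls (ambiguity codes other
#' than N).  Ties on length are broken by the earliest start.
#'
#' @inheritParams trimSlidingWindow
#' @return A \linkS4class{TrimWindow}.
#' @export
trimManualProfile <- function(read, params = trimParams("manual")) {
  q <- qualities(read)
  n <- length(q)
  chars <- .splitBases(bases(read))
  amb <- !(chars %in% c("A", "C", "G", "T"))
  mixed <- amb & chars != "N"
  if (n == 0L)
    return(.newTrimWindow(q, amb, 1L, 0L, params$minClearLength))

  lowCum <- cumsum(c(0L, as.integer(q <= params$lowQvThreshold)))
  ambCum <- cumsum(c(0L, as.integer(amb)))
  best <- c(1L, 0L)
  for (s in seq_len(n)) {
    lens <- seq_len(n - s + 1L)
    nLow <- lowCum[s + lens] - lowCum[s]
    nAmb <- ambCum[s + lens] - ambCum[s]
    valid <- (nLow < params$lowQvFractionCutoff * lens) &
             (nAmb <= params$maxUndeterminedFraction * lens)
    if (any(valid)) {
      len <- max(lens[valid])
      if (len > best[2L] - best[1L] + 1L) best <- c(s, s + len - 1L)
    }
    if (best[2L] - best[1L] + 1L >= n - s) break  # no longer window possible
  }
  win <- .newTrimWindow(q, amb, best[1L], best[2L], params$minClearLength)
  if (win@passed) {
    nMixed <- sum(mixed[win@start:win@end])
    if (nMixed > params$maxMixedBases) {
      win@passed <- FALSE
      win@reason <- sprintf("mixed bases %d > max_mixed_bases %d",
                            nMixed, params$maxMixedBases)
    }
  }
  win
}

#' Read-level QC on a trimmed window
#'
#' A read passes when its trim window passed (clear length reached) and the
#' mean QV over the retained bases strictly exceeds
#' \code{readMeanQvCutoff} (default 30).
#'
#' @param read A \linkS4class{SangerRead}.
#' @param window The \linkS4class{TrimWindow} for that read.
#' @param params A \code{\link{trimParams}} object.
#' @return List with elements \code{pass} (logical), \code{meanQV}, and
#'   \code{reasons} (character, empty when passing).
#' @export
readQC <- function(read, window, params = trimParams("automated")) {
  stopifnot(is(window, "TrimWindow"))
  if (window@end > length(qualities(read)))
    stop("trim window extends past the read")
  reasons <- character(0)
  if (!window@passed) reasons <- c(reasons, window@reason)
  mq <- window@meanQV
  if (!isTRUE(mq > params$readMeanQvCutoff))
    reasons <- c(reasons, sprintf("mean trimmed QV %s not > %s",
                                  format(mq), format(params$readMeanQvCutoff)))
  list(pass = length(reasons) == 0L, meanQV = mq, reasons = reasons)
}

#' Subset a read to its trimmed window
#'
#' @param read A \linkS4class{SangerRead}.
#' @param window A \linkS4class{TrimWindow} within the read.
#' @return The trimmed \linkS4class{SangerRead} (empty read if the window
#'   is empty).  Peak locations and traces are carried along.
#' @export
trimRead <- function(read, window) {
  stopifnot(is(window, "TrimWindow"))
  if (window@end < window@start)
    return(SangerRead(sampleId(read), direction(read), "", integer(0),
                      sourcePath = read@sourcePath))
  idx <- window@start:window@end
  SangerRead(sampleId(read), direction(read),
             substr(bases(read), window@start, window@end),
             qualities(read)[idx],
             peakLocations = if (length(peakLocations(read)))
               peakLocations(read)[idx] else integer(0),
             traces = if (nrow(traces(read))) traces(read) else NULL,
             sourcePath = read@sourcePath)
}

#' Call mixed bases from trace data
#'
#' At each basecall peak, if the second-highest trace channel reaches at
#' least \code{signalToNoise} times the highest channel, the base is
#' replaced by the IUPAC ambiguity code of the two channels.  Reads without
#' traces or peak locations are returned unchanged.
#'
#' @inheritParams trimSlidingWindow
#' @return The read with ambiguity codes substituted where a secondary
#'   peak crosses the ratio.
#' @export
callMixedBases <- function(read, params = trimParams("automated")) {
  tr <- traces(read)
  pk <- peakLocations(read)
  if (!nrow(tr) || !length(pk)) return(read)
  chars <- .splitBases(bases(read))
  chan <- c("A", "C", "G", "T")
  for (i in seq_along(chars)) {
    sig <- tr[pk[i], ]
    ord <- order(sig, decreasing = TRUE)
    if (sig[ord[1L]] > 0 &&
        sig[ord[2L]] >= params$signalToNoise * sig[ord[1L]]) {
      chars[i] <- .ambiguityCode(chan[ord[1L]], chan[ord[2L]])
    }
  }
  SangerRead(sampleId(read), direction(read), paste(chars, collapse = ""),
             qualities(read), peakLocations = pk, traces = tr,
             sourcePath = read@sourcePath)
}
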