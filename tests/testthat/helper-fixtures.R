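# Small fixture builders shared across test files.

randomDna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# a read with optional quality structure and ambiguity codes
randomRead <- function(n, qvModel = c("uniform", "ramp", "noisy"),
                       ambFrac = 0, id = "r1", direction = "forward") {
  qvModel <- match.arg(qvModel)
  q <- switch(qvModel,
    uniform = rep(sample(5:60, 1L), n),
    ramp = {
      r <- max(1L, n %/% 4L)
      as.integer(round(c(seq(8, 55, length.out = r),
                         rep(55, max(0L, n - 2L * r)),
                         seq(55, 8, length.out = r))))[seq_len(n)]
    },
    noisy = sample(0:62, n, replace = TRUE))
  chars <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (ambFrac > 0) {
    k <- rbinom(1L, n, ambFrac)
    if (k > 0L)
      chars[sample.int(n, k)] <- sample(c("N", "R", "Y", "M", "K"), k,
                                        replace = TRUE)
  }
  SangerRead(id, direction, paste(chars, collapse = ""), q)
}

# flat traces with one dominant peak per base and optional secondary peaks
flatTraceRead <- function(bases, secondaryAt = integer(0),
                          secondaryBase = "G", secondaryHeight = 0L,
                          qv = 50L) {
  chars <- strsplit(bases, "")[[1L]]
  n <- length(chars)
  tr <- matrix(0L, nrow = 10L * n, ncol = 4L,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  pk <- as.integer(10L * (seq_len(n) - 1L) + 5L)
  chan <- ifelse(chars %in% c("A", "C", "G", "T"), chars, "A")
  for (i in seq_len(n)) tr[pk[i], chan[i]] <- 1000L
  for (i in secondaryAt) tr[pk[i], secondaryBase] <- as.integer(secondaryHeight)
  SangerRead("t1", "forward", bases, rep(as.integer(qv), n),
             peakLocations = pk, traces = tr)
}

workedExamplePath <- function() {
  system.file("extdata", "worked_example_metrics.tsv",
              package = "sanger16S")
}
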