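autoP <- trimParams("automated")
manP <- trimParams("manual")

test_that("uniformly good and uniformly bad reads trim as expected", {
  good <- SangerRead("g", "forward", randomDna(100), rep(50L, 100L))
  w <- trimSlidingWindow(good, autoP)
  expect_identical(c(w@start, w@end), c(1L, 100L))
  expect_true(w@passed)

  bad <- SangerRead("b", "forward", randomDna(100), rep(10L, 100L))
  wb <- trimSlidingWindow(bad, autoP)
  expect_false(wb@passed)
  expect_match(wb@reason, "clear length")

  wm <- trimManualProfile(good, manP)
  expect_identical(c(wm@start, wm@end), c(1L, 100L))
  expect_true(wm@passed)
})

test_that("a ramped read matches the exhaustive-search oracle", {
  set.seed(501)
  q <- as.integer(c(round(seq(10, 10, length.out = 20)), rep(55L, 300),
                    rep(10L, 20)))
  r <- SangerRead("ramp", "forward", randomDna(length(q)), q)
  w <- trimSlidingWindow(r, autoP)
  expect_identical(c(w@start, w@end),
                   oracleTrimSliding(q, autoP$windowSize,
                                     autoP$windowQvCutoff))
})

test_that("low-QV bases spread through a read match the manual oracle", {
  set.seed(502)
  q <- rep(50L, 100L)
  q[seq(5L, 100L, by = 5L)] <- 20L      # 20% low-QV, evenly spread
  r <- SangerRead("lq", "forward", randomDna(100), q)
  w <- trimManualProfile(r, manP)
  o <- oracleTrimManual(q, strsplit(bases(r), "")[[1L]])
  expect_identical(c(w@start, w@end), o)
  # retained window must itself satisfy the <15% rule
  expect_lt(mean(q[w@start:w@end] <= 30), 0.15)
})

test_that("both trimmers equal exhaustive search on random reads", {
  set.seed(503)
  for (k in 1:120) {
    n <- sample(1:200, 1L)
    r <- randomRead(n, qvModel = sample(c("uniform", "ramp", "noisy"), 1L),
                    ambFrac = 0.08)
    w <- trimSlidingWindow(r, autoP)
    expect_identical(c(w@start, w@end),
                     oracleTrimSliding(qualities(r), autoP$windowSize,
                                       autoP$windowQvCutoff),
                     info = sprintf("sliding, read %d", k))
    wm <- trimManualProfile(r, manP)
    expect_identical(c(wm@start, wm@end),
                     oracleTrimManual(qualities(r),
                                      strsplit(bases(r), "")[[1L]]),
                     info = sprintf("manual, read %d", k))
  }
})

test_that("raising the QV cutoff never lengthens the sliding window", {
  set.seed(504)
  for (k in 1:40) {
    r <- randomRead(sample(10:200, 1L), qvModel = "noisy")
    prev <- Inf
    for (cutoff in c(20, 30, 40, 50)) {
      w <- trimSlidingWindow(r, trimParams("automated",
                                           windowQvCutoff = cutoff))
      expect_lte(length(w), prev)
      prev <- length(w)
    }
  }
})

test_that("trimming an already-trimmed read returns the full range", {
  set.seed(505)
  for (k in 1:25) {
    r <- randomRead(sample(30:200, 1L), qvModel = "ramp")
    w <- trimSlidingWindow(r, autoP)
    if (length(w) == 0L) next
    t1 <- trimRead(r, w)
    w2 <- trimSlidingWindow(t1, autoP)
    expect_identical(c(w2@start, w2@end), c(1L, length(t1)))
    wm <- trimManualProfile(r, manP)
    if (length(wm) == 0L) next
    t2 <- trimRead(r, wm)
    wm2 <- trimManualProfile(t2, manP)
    expect_identical(c(wm2@start, wm2@end), c(1L, length(t2)))
  }
})

test_that("degenerate reads are handled totally", {
  empty <- SangerRead("e", "forward", "", integer(0))
  w <- trimSlidingWindow(empty, autoP)
  expect_false(w@passed)
  expect_identical(length(w), 0L)
  short <- SangerRead("s", "forward", "ACGTA", rep(60L, 5L))
  ws <- trimSlidingWindow(short, autoP)     # shorter than one window
  expect_identical(c(ws@start, ws@end), c(1L, 5L))
  expect_false(ws@passed)                   # below min clear length
})

test_that("undetermined bases beyond 10% fail the manual profile", {
  b <- paste(c(rep("A", 15), rep("N", 30), rep("C", 15)), collapse = "")
  r <- SangerRead("n", "forward", b, rep(50L, 60L))
  w <- trimManualProfile(r, manP)
  expect_false(w@passed)
  # the surviving window cannot reach the 50-base clear length
  expect_lt(length(w), 50L)
})

test_that("excess mixed bases fail a window that otherwise passes", {
  b <- paste(c(rep("A", 30), rep("R", 25), rep("C", 45)), collapse = "")
  q <- rep(55L, 100L)
  r <- SangerRead("mx", "forward", b, q)
  # 25 mixed bases = 25% undetermined overall; relax the undetermined cap
  # so the mixed-base cap is what trips
  p <- trimParams("manual", maxUndeterminedFraction = 0.5)
  w <- trimManualProfile(r, p)
  expect_false(w@passed)
  expect_match(w@reason, "mixed bases")
})

test_that("read QC requires a passing window and mean QV strictly above 30", {
  r <- SangerRead("q", "forward", randomDna(100), rep(45L, 100L))
  w <- trimSlidingWindow(r, autoP)
  expect_true(readQC(r, w, autoP)$pass)

  r30 <- SangerRead("q30", "forward", randomDna(100), rep(30L, 100L))
  w30 <- trimManualProfile(r30, trimParams("manual", lowQvThreshold = 0))
  expect_identical(length(w30), 100L)      # window retained...
  qc <- readQC(r30, w30, manP)
  expect_false(qc$pass)                    # ...but mean QV 30 is not > 30
  expect_match(qc$reasons, "not >", all = FALSE)
})

test_that("secondary peaks at or above 0.33 of the primary become IUPAC codes", {
  r <- flatTraceRead("ACGTA", secondaryAt = integer(0))
  expect_identical(bases(callMixedBases(r, autoP)), "ACGTA")

  # A primary 1000 with C secondary 100 (ratio 0.1): stays A
  r1 <- flatTraceRead("AAAAA", secondaryAt = 2L, secondaryBase = "C",
                      secondaryHeight = 100L)
  expect_identical(bases(callMixedBases(r1, autoP)), "AAAAA")

  # A primary 1000 with G secondary 500 (ratio 0.5 >= 0.33): becomes R
  r2 <- flatTraceRead("AAAAA", secondaryAt = 3L, secondaryBase = "G",
                      secondaryHeight = 500L)
  expect_identical(bases(callMixedBases(r2, autoP)), "AARAA")

  # exactly at the 0.33 cutoff: called
  r3 <- flatTraceRead("CCCC", secondaryAt = 1L, secondaryBase = "T",
                      secondaryHeight = 330L)
  expect_identical(substr(bases(callMixedBases(r3, autoP)), 1L, 1L), "Y")

  # no traces: identity
  plain <- SangerRead("p", "forward", "ACGT", rep(40L, 4L))
  expect_identical(callMixedBases(plain, autoP), plain)
})
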