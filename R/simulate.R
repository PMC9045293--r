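# Synthetic data: divergence-controlled reference databases and
# forward/reverse Sanger read pairs with end-quality ramps, so every stage
# of the pipeline is testable without external downloads.

#' Simulation configuration
#'
#' Defaults emulate a partial 16S amplicon (~520 bp, the first ~500 bp of
#' the gene), genera separated by ~10\% sequence divergence with species
#' ~3\% apart within a genus, a 0.5\% per-base miscall rate in the
#' high-quality plateau (QV 55), and 25-base degraded ramps (down to QV
#' 10) at both read ends.
#'
#' @param nGenera Number of genera in the reference set.
#' @param speciesPerGenus Species per genus.
#' @param seqLength Template length in bases.
#' @param interGenusDivergence Approximate pairwise substitution fraction
#'   between genera.
#' @param intraGenusDivergence Approximate pairwise substitution fraction
#'   between species of one genus.
#' @param readErrorRate Per-base miscall probability in the high-quality
#'   plateau.
#' @param endRampLength Degraded bases at each read end.
#' @param qvHigh,qvLow Phred levels of the plateau and the ramp ends.
#' @param seed Integer seed; a fixed seed gives byte-identical outputs.
#' @return A list of class \code{"SimConfig"}.
#' @export
simConfig <- function(nGenera = 3L, speciesPerGenus = 3L, seqLength = 520L,
                      interGenusDivergence = 0.10,
                      intraGenusDivergence = 0.03,
                      readErrorRate = 0.005, endRampLength = 25L,
                      qvHigh = 55L, qvLow = 10L, seed = 1L) {
  cfg <- list(nGenera = as.integer(nGenera),
              speciesPerGenus = as.integer(speciesPerGenus),
              seqLength = as.integer(seqLength),
              interGenusDivergence = interGenusDivergence,
              intraGenusDivergence = intraGenusDivergence,
              readErrorRate = readErrorRate,
              endRampLength = as.integer(endRampLength),
              qvHigh = as.integer(qvHigh), qvLow = as.integer(qvLow),
              seed = as.integer(seed))
  stopifnot(cfg$nGenera >= 1L, cfg$speciesPerGenus >= 1L,
            cfg$seqLength >= 1L,
            cfg$readErrorRate >= 0, cfg$readErrorRate < 1,
            cfg$qvHigh >= 0L, cfg$qvHigh <= 62L,
            cfg$qvLow >= 0L, cfg$qvLow <= 62L)
  if (cfg$nGenera > 1L && (cfg$interGenusDivergence <= 0 ||
                           cfg$interGenusDivergence >= 0.5))
    stop("interGenusDivergence must be in (0, 0.5) with more than 1 genus")
  if (cfg$speciesPerGenus > 1L && (cfg$intraGenusDivergence <= 0 ||
                                   cfg$intraGenusDivergence >= 0.5))
    stop("intraGenusDivergence must be in (0, 0.5) with more than 1 species")
  class(cfg) <- "SimConfig"
  cfg
}

.randomSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# substitute a fraction p of positions (rounded) to a different base
.mutateSeq <- function(seq, p) {
  chars <- .splitBases(seq)
  k <- round(p * length(chars))
  if (k < 1L) return(seq)
  pos <- sample.int(length(chars), k)
  for (i in pos)
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  paste(chars, collapse = "")
}

.pairDivergence <- function(a, b) {
  ca <- .splitBases(a); cb <- .splitBases(b)
  mean(ca != cb)
}

#' Generate a synthetic reference database
#'
#' One root sequence per genus (diverged siblings of a common ancestor);
#' species are derived from their genus root by intra-genus substitutions.
#' Realized pairwise divergences are checked against the configured rates
#' (within +/-20\%) and the draw is repeated otherwise, so the database
#' reliably exercises the identity thresholds.
#'
#' @param cfg A \code{\link{simConfig}}.
#' @param dir Optional directory; when given, \code{refs.fasta},
#'   \code{taxonomy.tsv} and \code{truth.tsv} are written there.
#' @return List with \code{db} (a \linkS4class{ReferenceDB}) and
#'   \code{truth} (data.frame accession, genus, species, sequence).
#' @export
generateReferenceDB <- function(cfg = simConfig(), dir = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  set.seed(cfg$seed)
  tol <- 0.20
  for (attempt in seq_len(100L)) {
    ancestor <- .randomSeq(cfg$seqLength)
    roots <- vapply(seq_len(cfg$nGenera), function(i)
      .mutateSeq(ancestor, cfg$interGenusDivergence / 2), character(1))
    seqs <- character(0); genus <- character(0); species <- character(0)
    for (i in seq_len(cfg$nGenera)) {
      for (j in seq_len(cfg$speciesPerGenus)) {
        seqs <- c(seqs, if (cfg$speciesPerGenus == 1L) roots[i]
                  else .mutateSeq(roots[i], cfg$intraGenusDivergence / 2))
        genus <- c(genus, paste0("Genus", LETTERS[i]))
        species <- c(species, paste0("species", letters[j]))
      }
    }
    ok <- TRUE
    if (cfg$nGenera > 1L) {
      for (i in seq_len(cfg$nGenera - 1L)) for (k in (i + 1L):cfg$nGenera) {
        d <- .pairDivergence(roots[i], roots[k])
        if (d < (1 - tol) * cfg$interGenusDivergence ||
            d > (1 + tol) * cfg$interGenusDivergence) ok <- FALSE
      }
    }
    if (ok && cfg$speciesPerGenus > 1L) {
      for (i in seq_len(cfg$nGenera)) {
        idx <- which(genus == paste0("Genus", LETTERS[i]))
        for (a in seq_along(idx)[-length(idx)])
          for (b in (a + 1L):length(idx)) {
            d <- .pairDivergence(seqs[idx[a]], seqs[idx[b]])
            if (d < (1 - tol) * cfg$intraGenusDivergence ||
                d > (1 + tol) * cfg$intraGenusDivergence) ok <- FALSE
          }
      }
    }
    if (ok) break
    if (attempt == 100L)
      stop("could not realize the configured divergences in 100 attempts")
  }
  acc <- sprintf("SIM%03d", seq_along(seqs))
  names(seqs) <- acc
  tax <- data.frame(accession = acc, genus = genus, species = species,
                    group = NA_character_, stringsAsFactors = FALSE)
  truth <- data.frame(accession = acc, genus = genus, species = species,
                      sequence = unname(seqs), stringsAsFactors = FALSE)
  db <- ReferenceDB(seqs, tax, tier = "primary_16S")
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    writeFasta(seqs, file.path(dir, "refs.fasta"))
    writeTaxonomy(tax, file.path(dir, "taxonomy.tsv"))
    utils::write.table(truth, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  }
  list(db = db, truth = truth)
}

.qvProfile <- function(n, ramp, qvHigh, qvLow) {
  qv <- rep(qvHigh, n)
  ramp <- min(ramp, n %/% 2L)
  if (ramp > 0L) {
    up <- as.integer(round(seq(qvLow, qvHigh,
                               length.out = ramp + 1L)))[seq_len(ramp)]
    qv[seq_len(ramp)] <- up
    qv[(n - ramp + 1L):n] <- rev(up)
  }
  qv
}

.applyErrors <- function(chars, qv, plateauRate, qvHigh) {
  p <- ifelse(qv >= qvHigh, plateauRate, 10^(-qv / 10))
  hit <- stats::runif(length(chars)) < p
  for (i in which(hit))
    chars[i] <- sample(setdiff(c("A", "C", "G", "T"), chars[i]), 1L)
  chars
}

# Gaussian trace peaks on a 12-points-per-base raster; secondary peaks can
# be injected to exercise the mixed-base (0.33 ratio) rule.
.makeTraces <- function(chars, secondary = NULL, pointsPerBase = 12L,
                        amplitude = 1000, sigma = 2.5) {
  n <- length(chars)
  total <- pointsPerBase * n
  tr <- matrix(0, nrow = total, ncol = 4L,
               dimnames = list(NULL, c("A", "C", "G", "T")))
  centers <- pointsPerBase %/% 2L + pointsPerBase * (seq_len(n) - 1L)
  x <- seq_len(total)
  addPeak <- function(base, center, amp) {
    lo <- max(1L, center - 8L); hi <- min(total, center + 8L)
    tr[lo:hi, base] <<- tr[lo:hi, base] +
      amp * exp(-((x[lo:hi] - center)^2) / (2 * sigma^2))
  }
  for (i in seq_len(n)) {
    b <- chars[i]
    if (!b %in% c("A", "C", "G", "T")) b <- "A"  # placeholder channel
    addPeak(b, centers[i], amplitude)
  }
  if (!is.null(secondary)) {
    for (k in seq_along(secondary$pos))
      addPeak(secondary$base[k], centers[secondary$pos[k]],
              amplitude * secondary$ratio[k])
  }
  storage.mode(tr) <- "integer"
  list(traces = tr, peaks = as.integer(centers))
}

#' Simulate a forward/reverse Sanger read pair
#'
#' The forward read covers the template 5'->3'; the reverse read is the
#' reverse complement.  Both get a quality profile of low ramp, high
#' plateau, low ramp; miscalls are drawn at \code{readErrorRate} in the
#' plateau and at the Phred-implied rate (10^(-QV/10)) in the ramps.
#'
#' @param template Template DNA string (ACGT).
#' @param cfg A \code{\link{simConfig}}.
#' @param sampleId Sample identifier for both reads.
#' @param seed Optional seed for this pair; \code{NULL} continues the
#'   current RNG stream.
#' @param withTraces Also synthesize Gaussian trace peaks and peak
#'   locations (12 raster points per base).
#' @param secondaryPeaks Optional list(\code{pos}, \code{base},
#'   \code{ratio}) of secondary peaks to inject into the forward read's
#'   traces.
#' @return List with \code{forward} and \code{reverse}
#'   \linkS4class{SangerRead}s.
#' @export
simulateReadPair <- function(template, cfg = simConfig(),
                             sampleId = "sim", seed = NULL,
                             withTraces = FALSE, secondaryPeaks = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  if (nchar(template) < 2L * cfg$endRampLength + 50L)
    stop("template too short for the configured end ramps")
  if (!is.null(seed)) set.seed(seed)
  n <- nchar(template)
  qv <- .qvProfile(n, cfg$endRampLength, cfg$qvHigh, cfg$qvLow)

  mk <- function(seqStr, dirn) {
    chars <- .applyErrors(.splitBases(seqStr), qv, cfg$readErrorRate,
                          cfg$qvHigh)
    tr <- NULL; pk <- integer(0)
    if (withTraces) {
      t <- .makeTraces(chars,
                       secondary = if (dirn == "forward") secondaryPeaks)
      tr <- t$traces; pk <- t$peaks
    }
    SangerRead(sampleId, dirn, paste(chars, collapse = ""), qv,
               peakLocations = pk, traces = tr)
  }
  list(forward = mk(template, "forward"),
       reverse = mk(revComp(template), "reverse"))
}

#' End-to-end benchmark on simulated samples
#'
#' Generates a reference database from \code{cfg}, simulates read pairs
#' from randomly chosen truth species, runs the full pipeline (trim, QC,
#' merge, search, classify) on each, and scores the calls against the
#' truth using the concordance rules (genus-level agreement; inconclusive
#' results tracked separately).
#'
#' @param cfg A \code{\link{simConfig}}; \code{cfg$seed} fixes everything.
#' @param nSamples Number of simulated samples.
#' @param config Optional \code{\link{runConfig}} overriding trim/scoring/
#'   threshold parameters.
#' @return List with \code{fractionCorrectGenus},
#'   \code{fractionCorrectSpecies}, \code{fractionInconclusive}, and
#'   \code{perSample} (data.frame of truth vs call per sample).
#' @export
endToEndBenchmark <- function(cfg = simConfig(), nSamples = 100L,
                              config = NULL) {
  stopifnot(inherits(cfg, "SimConfig"))
  gen <- generateReferenceDB(cfg)
  if (is.null(config))
    config <- runConfig(primaryDb = gen$db, seed = cfg$seed,
                        logLevel = "quiet")
  else config$primaryDb <- gen$db
  # RNG continues deterministically from the database draw
  pick <- sample.int(nrow(gen$truth), nSamples, replace = TRUE)
  seeds <- sample.int(2^30, nSamples)

  rows <- vector("list", nSamples)
  for (s in seq_len(nSamples)) {
    tr <- gen$truth[pick[s], ]
    pair <- simulateReadPair(tr$sequence, cfg,
                             sampleId = sprintf("sim%03d", s),
                             seed = seeds[s])
    out <- identifyFromReads(pair$forward, pair$reverse, config)
    res <- out$result
    m <- metrics(res)
    callGenus <- if (category(res) %in% c("species", "genus"))
      m$topGenus else NA_character_
    rows[[s]] <- data.frame(
      sample_id = sprintf("sim%03d", s),
      truth_genus = tr$genus, truth_species = tr$species,
      category = category(res),
      call_genus = if (is.null(callGenus)) NA_character_ else callGenus,
      call_species = if (category(res) == "species")
        m$topSpecies else NA_character_,
      correct_genus = identical(callGenus, tr$genus),
      correct_species = category(res) == "species" &&
        identical(m$topSpecies, tr$species) &&
        identical(m$topGenus, tr$genus),
      stringsAsFactors = FALSE)
  }
  per <- do.call(rbind, rows)
  list(fractionCorrectGenus = mean(per$correct_genus),
       fractionCorrectSpecies = mean(per$correct_species),
       fractionInconclusive = mean(per$category %in%
                                   c("inconclusive", "excluded")),
       perSample = per)
}
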