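mkM <- function(alen, cover, id, dist = NA_real_, genus = "Selenomonas",
                species = "infelix", group = NA_character_) {
  idMetrics(alen, cover, id, dist, topGenus = genus, topSpecies = species,
            topGroup = group)
}

catRank <- c(inconclusive = 1L, genus = 2L, species = 3L)

test_that("classification reproduces representative worked examples", {
  r1 <- classify(mkM(509, 99, 99.5, 1.5))
  expect_identical(category(r1), "species")
  expect_identical(reportedName(r1), "Selenomonas infelix")
  expect_length(qcReasons(r1), 0L)

  r2 <- classify(mkM(488, 99, 99.0, 0.7, genus = "Comamonas",
                     species = "kerstersii"))
  expect_identical(category(r2), "genus")
  expect_identical(reportedName(r2), "Comamonas sp.")
  expect_match(qcReasons(r2), "distance", all = FALSE)

  r3 <- classify(mkM(476, 98, 96.2, NA, genus = "Parvimonas",
                     species = "micra"))
  expect_identical(category(r3), "inconclusive")
  expect_match(qcReasons(r3), "identity < 97", all = FALSE)

  r4 <- classify(mkM(427, 98, 98.9, 0.5, genus = "Corynebacterium",
                     species = "diphtheriae"))
  expect_identical(category(r4), "inconclusive")
  expect_match(qcReasons(r4), "400-440", all = FALSE)
})

test_that("every species-tier boundary is inclusive exactly as stated", {
  # all thresholds exactly met -> species
  expect_identical(category(classify(mkM(441, 98, 99, 0.8))), "species")
  # each threshold just missed
  expect_identical(category(classify(mkM(440, 98, 99, 0.8))), "genus")
  expect_identical(category(classify(mkM(441, 97.9, 99, 0.8))),
                   "inconclusive")
  expect_identical(category(classify(mkM(441, 98, 98.9, 0.8))), "genus")
  expect_identical(category(classify(mkM(441, 98, 99, 0.79))), "genus")
  # the 97 identity floor
  expect_identical(category(classify(mkM(441, 98, 97, 0.5))), "genus")
  expect_identical(category(classify(mkM(441, 98, 96.9, 0.5))),
                   "inconclusive")
  # the medium band caps at genus
  expect_identical(category(classify(mkM(400, 98, 99, 5))), "genus")
  expect_identical(category(classify(mkM(400, 98, 98.9, 5))),
                   "inconclusive")
  # below 400: always inconclusive
  expect_identical(category(classify(mkM(399, 100, 100, 5))),
                   "inconclusive")
})

test_that("an unmeasurable distance caps the call at genus", {
  r <- classify(mkM(466, 98, 99.7, NA, genus = "Parvimonas",
                    species = "micra"))
  expect_identical(category(r), "genus")
  expect_match(qcReasons(r), "not measurable", all = FALSE)
})

test_that("group labels override the binomial in genus-level reports", {
  r <- classify(mkM(412, 100, 99.3, 0.2, genus = "Streptococcus",
                    species = "mitis", group = "S. mitis group"))
  expect_identical(category(r), "genus")
  expect_identical(reportedName(r), "S. mitis group")
})

test_that("classify is total and deterministic over the metric space", {
  set.seed(801)
  for (k in 1:400) {
    m <- mkM(sample(0:600, 1L), round(runif(1, 0, 100), 1L),
             round(runif(1, 80, 100), 1L),
             if (runif(1) < 0.2) NA_real_ else round(runif(1, 0, 5), 1L))
    r <- classify(m)
    expect_true(category(r) %in% c("species", "genus", "inconclusive"))
    if (category(r) == "inconclusive") expect_gt(length(qcReasons(r)), 0L)
    if (category(r) == "species") expect_length(qcReasons(r), 0L)
    expect_identical(category(classify(m)), category(r))
  }
})

test_that("improving identity, cover or distance never demotes the call", {
  set.seed(802)
  for (k in 1:250) {
    m <- mkM(sample(380:600, 1L), round(runif(1, 90, 100), 1L),
             round(runif(1, 94, 100), 1L), round(runif(1, 0, 2), 1L))
    base <- catRank[[category(classify(m))]]
    up <- m; up$percentIdentity <- min(100, up$percentIdentity + runif(1, 0, 4))
    expect_gte(catRank[[category(classify(up))]], base)
    up <- m; up$queryCover <- min(100, up$queryCover + runif(1, 0, 4))
    expect_gte(catRank[[category(classify(up))]], base)
    up <- m; up$distanceNextSpecies <- up$distanceNextSpecies + runif(1, 0, 2)
    expect_gte(catRank[[category(classify(up))]], base)
  }
})

test_that("report rows carry the comment convention and QC context", {
  g <- classify(mkM(487, 99, 98.4, 0.2, genus = "Acinetobacter",
                    species = "seifertii"))
  row <- renderReportRow(g, "s1", list(fwdQc = "pass", revQc = "pass",
                                       provenance = "consensus",
                                       consensusLength = 490L,
                                       lengthCategory = "long"))
  expect_identical(row$comment, "most closely related to Acinetobacter seifertii")
  expect_identical(row$category, "genus")
  expect_identical(row$reported_name, "Acinetobacter sp.")
  expect_identical(row$fwd_qc, "pass")

  s <- classify(mkM(509, 99, 99.5, 1.5))
  expect_identical(renderReportRow(s, "s2")$comment, "")

  ex <- excludedResult("consensus 395 bp < 400 bp (short sequence)")
  rowEx <- renderReportRow(ex, "s3")
  expect_identical(rowEx$category, "excluded")
  expect_true(is.na(rowEx$percent_identity))
  expect_true(is.na(rowEx$aligned_length))
})

test_that("QC reasons in the report exactly justify the category", {
  set.seed(803)
  for (k in 1:100) {
    m <- mkM(sample(380:600, 1L), round(runif(1, 90, 100), 1L),
             round(runif(1, 94, 100), 1L),
             if (runif(1) < 0.2) NA_real_ else round(runif(1, 0, 2), 1L))
    r <- classify(m)
    row <- renderReportRow(r, "x")
    if (category(r) == "species") {
      expect_identical(row$qc_reasons, "")
    } else {
      expect_gt(nchar(row$qc_reasons), 0L)
    }
  }
})

test_that("concordance compares at genus level and omits inconclusives", {
  g <- classify(mkM(454, 99, 98.7, 2.0, genus = "Fusobacterium",
                    species = "necrophorum"))
  expect_identical(concordance(g, "Fusobacterium necrophorum"),
                   "concordant")
  expect_identical(concordance(g, "Fusobacterium sp."), "concordant")
  expect_identical(concordance(g, "Bacteroides fragilis"), "discordant")

  inc <- classify(mkM(395, 100, 100, 0.3))
  expect_identical(concordance(inc, "Streptococcus pneumoniae"), "omitted")
  expect_identical(concordance(excludedResult("failed"), "Anything sp."),
                   "omitted")

  s <- classify(mkM(509, 99, 99.5, 1.5, genus = "Staphylococcus",
                    species = "lentus"))
  expect_identical(concordance(s, "Propionibacteriaceae"), "discordant")

  expect_error(concordance(g, ""), "unparseable")
  expect_error(concordance(g, "   "), "unparseable")
})
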