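mkDb <- function(seqs, genus = NULL, species = NULL, group = NULL,
                 tier = "primary_16S") {
  n <- length(seqs)
  if (is.null(names(seqs))) names(seqs) <- sprintf("ACC%03d", seq_len(n))
  if (is.null(genus)) genus <- rep("GenusA", n)
  if (is.null(species)) species <- paste0("species", letters[seq_len(n)])
  tax <- data.frame(accession = names(seqs), genus = genus,
                    species = species,
                    group = if (is.null(group)) NA_character_ else group,
                    stringsAsFactors = FALSE)
  ReferenceDB(seqs, tax, tier = tier)
}

mkRecord <- function(seq, id = "q1") {
  ConsensusRecord(id, seq, rep(50L, nchar(seq)), "consensus",
                  overlapLength = nchar(seq))
}

test_that("localAlign reports BLAST-style metrics on simple cases", {
  set.seed(701)
  s <- randomDna(450)
  a <- localAlign(s, s)
  expect_identical(a$percentIdentity, 100)
  expect_identical(a$alignedLength, 450L)
  expect_identical(c(a$queryStart, a$queryEnd), c(1L, 450L))

  # 5 substitutions over a 500-column gapless alignment -> 99.0
  q <- strsplit(randomDna(500), "")[[1L]]
  subj <- q
  for (i in c(100L, 200L, 300L, 350L, 400L))
    subj[i] <- setdiff(c("A", "C", "G", "T"), q[i])[1L]
  a2 <- localAlign(paste(q, collapse = ""), paste(subj, collapse = ""))
  expect_identical(a2$alignedLength, 500L)
  expect_identical(a2$matches, 495L)
  expect_identical(a2$percentIdentity, 99.0)
})

test_that("localAlign equals the DP oracle on random short pairs", {
  set.seed(702)
  for (k in 1:80) {
    a <- randomDna(sample(1:30, 1L))
    b <- randomDna(sample(1:30, 1L))
    got <- localAlign(a, b)
    ora <- oracleLocalAlign(a, b)
    expect_identical(got$score, ora$score, info = paste(a, b))
    expect_identical(got$matches, ora$matches, info = paste(a, b))
    expect_identical(got$alignedLength, ora$alignedLength,
                     info = paste(a, b))
    expect_identical(got$queryStart, ora$queryStart, info = paste(a, b))
    expect_identical(got$queryEnd, ora$queryEnd, info = paste(a, b))
  }
})

test_that("localAlign scores agree with an independent aligner", {
  set.seed(703)
  alpha <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K", "V", "H",
             "D", "B", "N")
  subst <- matrix(-2, 15, 15, dimnames = list(alpha, alpha))
  diag(subst) <- 1
  for (k in 1:25) {
    a <- randomDna(sample(40:120, 1L))
    b <- randomDna(sample(40:120, 1L))
    got <- localAlign(a, b)
    if (got$score <= 0) next
    ref <- Biostrings::pairwiseAlignment(
      Biostrings::DNAString(a), Biostrings::DNAString(b), type = "local",
      substitutionMatrix = subst, gapOpening = 5, gapExtension = 2)
    expect_equal(got$score, Biostrings::score(ref), info = paste(a, b))
  }
})

test_that("alignment metrics are invariant under reverse-complementing both", {
  set.seed(704)
  # unrelated sequences: the optimal score is strand-symmetric
  for (k in 1:15) {
    q <- randomDna(120); s <- randomDna(150)
    expect_identical(localAlign(q, s)$score,
                     localAlign(revComp(q), revComp(s))$score)
  }
  # homologous pairs (the regime the pipeline operates in): the optimum
  # is unique, so identity and span length are strand-symmetric too
  for (k in 1:15) {
    s <- randomDna(300)
    ch <- strsplit(s, "")[[1L]]
    for (p in sample.int(300, 6)) ch[p] <- setdiff(c("A", "C", "G", "T"),
                                                   ch[p])[1L]
    q <- substr(paste(ch, collapse = ""), 31L, 270L)
    a1 <- localAlign(q, s)
    a2 <- localAlign(revComp(q), revComp(s))
    expect_identical(a1$score, a2$score)
    expect_identical(a1$percentIdentity, a2$percentIdentity)
    expect_identical(a1$alignedLength, a2$alignedLength)
  }
})

test_that("searchDatabase ranks an exact match first and is deterministic", {
  set.seed(705)
  tpl <- randomDna(500)
  far <- vapply(1:3, function(i) {
    ch <- strsplit(tpl, "")[[1L]]
    pos <- sample.int(500, 40)            # ~8% diverged
    for (p in pos) ch[p] <- setdiff(c("A", "C", "G", "T"), ch[p])[1L]
    paste(ch, collapse = "")
  }, character(1))
  db <- mkDb(c(tpl, far))
  ht <- searchDatabase(mkRecord(tpl), db)
  h <- hits(ht)
  expect_identical(h$accession[1L], "ACC001")
  expect_identical(h$percentIdentity[1L], 100)
  expect_identical(h$queryCover[1L], 100)
  ht2 <- searchDatabase(mkRecord(tpl), db)
  expect_identical(hits(ht2), h)
})

test_that("duplicate database records tie-break by ascending accession", {
  set.seed(706)
  tpl <- randomDna(450)
  db <- mkDb(stats::setNames(c(tpl, tpl), c("ZZZ001", "AAA001")))
  h <- hits(searchDatabase(mkRecord(tpl), db))
  expect_identical(h$accession[1:2], c("AAA001", "ZZZ001"))
})

test_that("short queries and empty databases are refused", {
  set.seed(707)
  db <- mkDb(randomDna(500))
  shortRec <- mkRecord(randomDna(395))
  expect_identical(lengthCategory(shortRec), "short")
  expect_error(searchDatabase(shortRec, db), "short")
  emptyDb <- ReferenceDB(character(0),
                         data.frame(accession = character(0),
                                    genus = character(0),
                                    species = character(0),
                                    group = character(0)))
  expect_error(searchDatabase(mkRecord(randomDna(450)), emptyDb), "empty")
})

test_that("BLAST tabular files parse into ranked hit tables", {
  tax <- data.frame(accession = c("acc1", "acc2"),
                    genus = c("Selenomonas", "Selenomonas"),
                    species = c("infelix", "sputigena"),
                    group = NA_character_, stringsAsFactors = FALSE)
  p <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# query_length: 510",
               "q1\tacc1\t99.5\t509\t1\t505\t0.0\t900"), p)
  ht <- parseBlastTabular(p, tax)
  h <- hits(ht)
  expect_identical(h$percentIdentity, 99.5)
  expect_identical(h$alignedLength, 509L)
  expect_identical(h$queryCover, 99)     # 505/510 -> 99
  expect_identical(h$genus, "Selenomonas")

  # out-of-order rows are re-sorted by bitscore
  writeLines(c("q1\tacc2\t97.0\t480\t1\t480\t0.0\t700",
               "q1\tacc1\t99.5\t509\t1\t505\t0.0\t900"), p)
  h2 <- hits(parseBlastTabular(p, tax, queryLength = 510L))
  expect_identical(h2$accession, c("acc1", "acc2"))

  # empty file -> empty table
  file.create(p2 <- withr::local_tempfile(fileext = ".tsv"))
  expect_identical(length(parseBlastTabular(p2, tax, queryLength = 500L)),
                   0L)

  # unknown accession kept with a warning
  writeLines("q1\taccX\t98.0\t450\t1\t450\t0.0\t800", p)
  expect_warning(htU <- parseBlastTabular(p, tax, queryLength = 500L),
                 "taxonomy")
  expect_identical(hits(htU)$genus, "unknown")
})

test_that("distance to next species follows the top-identity definition", {
  mkHt <- function(df) HitTable("q1", transform(df,
    accession = sprintf("A%02d", seq_len(nrow(df))),
    group = NA_character_, alignedLength = 450L, queryCover = 99,
    score = rev(seq_len(nrow(df)))))
  d1 <- distanceToNextSpecies(mkHt(data.frame(
    genus = "G", species = c("x", "x", "y"),
    percentIdentity = c(99.5, 99.1, 98.0))))
  expect_identical(d1$value, 1.5)
  expect_identical(d1$nextSpecies, "G y")

  d2 <- distanceToNextSpecies(mkHt(data.frame(
    genus = "G", species = c("x", "x"),
    percentIdentity = c(99.5, 99.0))))
  expect_true(is.na(d2$value))

  d3 <- distanceToNextSpecies(mkHt(data.frame(
    genus = "G", species = c("x", "y"),
    percentIdentity = c(98.8, 98.8))))
  expect_identical(d3$value, 0)
})

test_that("species-group labels pool hits for the distance computation", {
  h <- data.frame(accession = c("A1", "A2", "A3"),
                  genus = "Streptococcus",
                  species = c("mitis", "pneumoniae", "pyogenes"),
                  group = c("S. mitis group", "S. mitis group", NA),
                  alignedLength = 450L, percentIdentity = c(99.3, 99.0, 96.0),
                  queryCover = 100, score = c(800, 790, 600),
                  stringsAsFactors = FALSE)
  d <- distanceToNextSpecies(HitTable("q1", h))
  expect_identical(d$topSpecies, "S. mitis group")
  expect_identical(d$value, 3.3)          # 99.3 - 96.0, pyogenes is next
  # without the pooling, pneumoniae would be the next species at 0.3
  h$group <- NA_character_
  d2 <- distanceToNextSpecies(HitTable("q1", h))
  expect_identical(d2$value, 0.3)
})

test_that("distance is non-negative and zero only on ties", {
  set.seed(708)
  for (k in 1:30) {
    n <- sample(2:8, 1L)
    h <- data.frame(accession = sprintf("A%02d", 1:n),
                    genus = "G",
                    species = sample(letters[1:3], n, replace = TRUE),
                    group = NA_character_, alignedLength = 450L,
                    percentIdentity = round(runif(n, 90, 100), 1L),
                    queryCover = 100,
                    score = round(runif(n, 500, 900)),
                    stringsAsFactors = FALSE)
    d <- distanceToNextSpecies(HitTable("q1", h))
    if (is.na(d$value)) next
    expect_gte(d$value, 0)
    if (d$value == 0) {
      best <- tapply(h$percentIdentity, paste(h$genus, h$species), max)
      expect_gte(sum(best == max(best)), 2L)
    }
  }
})

test_that("the broad tier is consulted only when the primary is inconclusive", {
  set.seed(709)
  tpl <- randomDna(500)
  # primary reference misses the last 15 query bases -> cover 97
  primary <- mkDb(stats::setNames(substr(tpl, 1L, 485L), "P001"),
                  genus = "GenusA", species = "speciesa")
  broad <- mkDb(stats::setNames(tpl, "B001"), genus = "GenusA",
                species = "speciesa", tier = "fallback_broad")
  rec <- mkRecord(tpl)
  fb <- fallbackSearch(rec, primary, broad)
  expect_identical(fb$tier, "fallback_broad")
  expect_identical(category(fb$result), "genus")
  expect_identical(hits(fb$hitTable)$queryCover[1L], 100)

  # conclusive primary: broad never used
  primaryFull <- mkDb(stats::setNames(tpl, "P001"), genus = "GenusA",
                      species = "speciesa")
  fb2 <- fallbackSearch(rec, primaryFull, broad)
  expect_identical(fb2$tier, "primary_16S")

  # no broad database: primary result returned with a note
  fb3 <- fallbackSearch(rec, primary, NULL)
  expect_identical(fb3$tier, "primary_16S")
  expect_match(fb3$note, "no broad database")

  # inconclusive at both tiers
  shortBroad <- mkDb(stats::setNames(substr(tpl, 1L, 485L), "B001"),
                     genus = "GenusA", species = "speciesa",
                     tier = "fallback_broad")
  fb4 <- fallbackSearch(rec, primary, shortBroad)
  expect_identical(fb4$tier, "fallback_broad")
  expect_identical(category(fb4$result), "inconclusive")
})
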