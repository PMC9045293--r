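# Internal helpers shared across modules.

IUPAC_LETTERS <- c("A", "C", "G", "T", "M", "R", "W", "S", "Y", "K",
                   "V", "H", "D", "B", "N")

.isIUPAC <- function(x) {
  nchar(x) == 0L || grepl("^[ACGTMRWSYKVHDBN]*$", x)
}

.splitBases <- function(x) {
  if (nchar(x) == 0L) character(0) else strsplit(x, "", fixed = TRUE)[[1L]]
}

#' Reverse complement of an IUPAC DNA string
#'
#' Standard reverse complement over the full IUPAC nucleotide alphabet
#' (R<->Y, K<->M, S and W self-complementary, N unchanged).
#'
#' @param seq A character scalar over the IUPAC DNA alphabet (uppercase).
#' @return The reverse-complemented string.
#' @examples
#' revComp("ACGT")   # "ACGT"
#' revComp("AAR")    # "YTT"
#' @export
revComp <- function(seq) {
  stopifnot(is.character(seq), length(seq) == 1L, !is.na(seq))
  seq <- toupper(seq)
  if (!.isIUPAC(seq))
    stop("sequence contains non-IUPAC characters")
  if (nchar(seq) == 0L) return(seq)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# IUPAC code for the union of the base sets of two (possibly ambiguous) codes.
.ambiguityCode <- function(b1, b2) {
  map <- Biostrings::IUPAC_CODE_MAP
  s1 <- strsplit(map[[b1]], "")[[1L]]
  s2 <- strsplit(map[[b2]], "")[[1L]]
  u <- paste(sort(unique(c(s1, s2))), collapse = "")
  names(map)[match(u, map)]
}

# Scoring matrix over the IUPAC alphabet: +match on exact letter equality,
# mismatch otherwise.  Ambiguity codes are never treated as fuzzy matches;
# the decision thresholds assume BLAST-like strict identity.
.substMatrix <- function(match = 1, mismatch = -2) {
  m <- matrix(mismatch, length(IUPAC_LETTERS), length(IUPAC_LETTERS),
              dimnames = list(IUPAC_LETTERS, IUPAC_LETTERS))
  diag(m) <- match
  m
}

# round() uses banker's rounding; alignment metrics are reported with
# conventional half-up rounding so printed values match field convention.
.roundHalfUp <- function(x, digits = 0L) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}
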