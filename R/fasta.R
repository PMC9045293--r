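# FASTA and taxonomy-table IO (thin wrappers over Biostrings).

#' Read a FASTA file
#'
#' @param path Path to a FASTA file (wrapped or unwrapped lines).
#' @return Named character vector of uppercase sequences; names are the
#'   full record identifiers.  An empty file yields an empty vector.
#'   Duplicate identifiers are kept, with a warning.
#' @export
readFasta <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0L) return(stats::setNames(character(0), NULL))
  set <- Biostrings::readBStringSet(path)
  out <- toupper(as.character(set))
  if (anyDuplicated(names(out)))
    warning("duplicate FASTA identifiers in ", path, "; all records kept")
  out
}

#' Write sequences as FASTA
#'
#' Sequences are written uppercase at a fixed line width; any width
#' re-parses to the same records.
#'
#' @param records Named character vector of sequences (names are record
#'   identifiers).
#' @param path Output path.
#' @param width Line-wrap width in bases (default 70).
#' @return \code{path}, invisibly.
#' @export
writeFasta <- function(records, path, width = 70L) {
  stopifnot(is.character(records))
  con <- tryCatch(file(path, "wt"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  ids <- names(records)
  if (is.null(ids)) ids <- paste0("seq", seq_along(records))
  for (i in seq_along(records)) {
    writeLines(paste0(">", ids[i]), con)
    s <- toupper(records[[i]])
    n <- nchar(s)
    if (n == 0L) next
    starts <- seq(1L, n, by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1L, n)), con)
  }
  invisible(path)
}

#' Read a taxonomy table
#'
#' Tab-separated, no header: accession, genus, species, optional group
#' label (a species complex such as "mitis group" that is reported in place
#' of a binomial).
#'
#' @param path Path to the TSV file.
#' @return data.frame with columns accession, genus, species, group.
#' @export
readTaxonomy <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (file.info(path)$size == 0L)
    return(data.frame(accession = character(0), genus = character(0),
                      species = character(0), group = character(0),
                      stringsAsFactors = FALSE))
  tab <- utils::read.delim(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE,
                           colClasses = "character")
  if (ncol(tab) < 3L)
    stop("taxonomy file needs at least 3 columns ",
         "(accession, genus, species): ", path)
  if (ncol(tab) == 3L) tab$V4 <- NA_character_
  tab <- tab[, 1:4]
  names(tab) <- c("accession", "genus", "species", "group")
  tab$group[!is.na(tab$group) & tab$group == ""] <- NA_character_
  tab
}

#' Write a taxonomy table
#'
#' @param taxonomy data.frame with columns accession, genus, species and
#'   optionally group.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeTaxonomy <- function(taxonomy, path) {
  if (is.null(taxonomy$group)) taxonomy$group <- NA_character_
  tab <- taxonomy[, c("accession", "genus", "species", "group")]
  tab$group[is.na(tab$group)] <- ""
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Load a reference database from FASTA + taxonomy files
#'
#' @param fastaPath Reference sequences (FASTA; record ids are accessions).
#' @param taxonomyPath Taxonomy TSV (see \code{\link{readTaxonomy}}).
#' @param tier Database tier, \code{"primary_16S"} or
#'   \code{"fallback_broad"}.
#' @return A \linkS4class{ReferenceDB}.
#' @export
readReferenceDB <- function(fastaPath, taxonomyPath, tier = "primary_16S") {
  seqs <- readFasta(fastaPath)
  tax <- readTaxonomy(taxonomyPath)
  ReferenceDB(seqs, tax, tier = tier)
}
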