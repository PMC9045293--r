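# Minimal ABIF (.ab1) container support.
#
# ABIF is the Applied Biosystems chromatogram format: a 4-byte "ABIF" magic,
# a 2-byte version, a 28-byte header entry describing the tag directory, and
# big-endian directory entries of 28 bytes each.  Only the tags this
# pipeline consumes are implemented: basecalls (PBAS), per-base quality
# values (PCON), peak locations (PLOC), the four processed trace channels
# (DATA 9-12) with their channel order (FWO_), and the sample name (SMPL).
# All other tags are ignored on read and omitted on write.

.ABIF_TYPE <- c(byte = 1L, char = 2L, short = 4L, long = 5L, pString = 18L)

# ---- big-endian packing helpers -------------------------------------------

.beUnpack <- function(raw, signed = TRUE) {
  n <- length(raw)
  v <- 0
  for (b in as.integer(raw)) v <- v * 256 + b
  if (signed && v >= 2^(8 * n - 1)) v <- v - 2^(8 * n)
  v
}

.bePack <- function(value, size) {
  value <- as.numeric(value)
  if (value < 0) value <- value + 2^(8 * size)
  out <- raw(size)
  for (i in seq_len(size)) {
    out[size - i + 1L] <- as.raw(value %% 256)
    value <- value %/% 256
  }
  out
}

.bePackVec <- function(values, size) {
  if (!length(values)) return(raw(0))
  do.call(c, lapply(values, .bePack, size = size))
}

.beUnpackVec <- function(raw, size, signed = TRUE) {
  n <- length(raw) %/% size
  vapply(seq_len(n), function(i)
    .beUnpack(raw[((i - 1L) * size + 1L):(i * size)], signed = signed),
    numeric(1))
}

# ---- reading ---------------------------------------------------------------

.abifDirectory <- function(dat, path) {
  if (length(dat) < 34L || rawToChar(dat[1:4]) != "ABIF")
    stop("not an ABIF file (bad magic): ", path)
  nEntries <- .beUnpack(dat[19:22])
  dirOffset <- .beUnpack(dat[27:30])
  if (nEntries < 0 || dirOffset < 0 ||
      dirOffset + 28 * nEntries > length(dat))
    stop("malformed ABIF directory (truncated file?): ", path)
  entries <- vector("list", nEntries)
  for (i in seq_len(nEntries)) {
    off <- dirOffset + (i - 1L) * 28L
    e <- dat[(off + 1L):(off + 28L)]
    name <- rawToChar(e[1:4])
    number <- .beUnpack(e[5:8])
    elemType <- .beUnpack(e[9:10])
    elemSize <- .beUnpack(e[11:12])
    numElem <- .beUnpack(e[13:16])
    dataSize <- .beUnpack(e[17:20])
    data <- if (dataSize <= 4L) {
      e[21:(20L + max(dataSize, 0L))]
    } else {
      dOff <- .beUnpack(e[21:24])
      if (dOff < 0 || dOff + dataSize > length(dat))
        stop(sprintf("ABIF tag %s.%d points outside the file: %s",
                     name, number, path))
      dat[(dOff + 1L):(dOff + dataSize)]
    }
    entries[[i]] <- list(name = name, number = number, elemType = elemType,
                         elemSize = elemSize, numElem = numElem, data = data)
  }
  entries
}

.abifTag <- function(entries, name, number) {
  for (e in entries)
    if (e$name == name && e$number == number) return(e)
  NULL
}

.abifDecode <- function(e) {
  if (is.null(e)) return(NULL)
  switch(as.character(e$elemType),
    "1" = as.integer(.beUnpackVec(e$data, 1L, signed = FALSE)),
    "2" = rawToChar(e$data),
    "4" = as.integer(.beUnpackVec(e$data, 2L)),
    "5" = as.integer(.beUnpackVec(e$data, 4L)),
    "18" = if (length(e$data) > 1L)
             rawToChar(e$data[-1L]) else "",
    stop("unsupported ABIF element type ", e$elemType,
         " for tag ", e$name))
}

#' Read an ABIF (.ab1) chromatogram
#'
#' Parses the basecalls, per-base quality values and, when present, the four
#' processed trace channels and peak locations from an ABIF container.
#' The read direction is not stored in ABIF, so it must be supplied by the
#' caller (typically from a sample manifest).
#'
#' @param path Path to an .ab1 file.
#' @param direction Read direction, \code{"forward"} (default) or
#'   \code{"reverse"}.
#' @param sampleId Sample identifier; defaults to the SMPL tag when present,
#'   otherwise the file name without extension.
#' @return A \linkS4class{SangerRead}.
#' @seealso \code{\link{writeABIF}}
#' @export
readABIF <- function(path, direction = "forward", sampleId = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  dat <- readBin(path, "raw", n = file.info(path)$size)
  entries <- .abifDirectory(dat, path)

  basesTag <- .abifTag(entries, "PBAS", 1L)
  if (is.null(basesTag)) basesTag <- .abifTag(entries, "PBAS", 2L)
  if (is.null(basesTag))
    stop("ABIF file has no basecall tag (PBAS): ", path)
  basesStr <- .abifDecode(basesTag)

  qualTag <- .abifTag(entries, "PCON", 1L)
  if (is.null(qualTag)) qualTag <- .abifTag(entries, "PCON", 2L)
  if (is.null(qualTag))
    stop("ABIF file has no per-base quality tag (PCON); ",
         "quality values are required: ", path)
  # decoded from the raw bytes: QV 0 is a legal value (nul byte)
  quals <- as.integer(qualTag$data)

  plocTag <- .abifTag(entries, "PLOC", 1L)
  if (is.null(plocTag)) plocTag <- .abifTag(entries, "PLOC", 2L)
  peaks <- if (is.null(plocTag)) integer(0) else .abifDecode(plocTag)

  fwo <- .abifDecode(.abifTag(entries, "FWO_", 1L))
  traceMat <- NULL
  chans <- lapply(9:12, function(k) .abifDecode(.abifTag(entries, "DATA", k)))
  if (!any(vapply(chans, is.null, logical(1)))) {
    order <- if (is.null(fwo)) c("G", "A", "T", "C") else .splitBases(fwo)
    traceMat <- matrix(0L, nrow = length(chans[[1L]]), ncol = 4L,
                       dimnames = list(NULL, c("A", "C", "G", "T")))
    for (k in 1:4) traceMat[, order[k]] <- chans[[k]]
  }

  if (is.null(sampleId)) {
    smpl <- .abifDecode(.abifTag(entries, "SMPL", 1L))
    sampleId <- if (!is.null(smpl) && nzchar(smpl)) smpl
                else tools::file_path_sans_ext(basename(path))
  }

  SangerRead(sampleId = sampleId, direction = direction, bases = basesStr,
             qualities = quals,
             peakLocations = if (length(peaks)) peaks else integer(0),
             traces = traceMat, sourcePath = path)
}

# ---- writing ---------------------------------------------------------------

.abifEntryRaw <- function(name, number, type, elemSize, numElem, data,
                          offset) {
  dataSize <- length(data)
  c(charToRaw(sprintf("%-4s", name)),
    .bePack(number, 4L), .bePack(type, 2L), .bePack(elemSize, 2L),
    .bePack(numElem, 4L), .bePack(dataSize, 4L),
    if (dataSize <= 4L) c(data, raw(4L - dataSize)) else .bePack(offset, 4L),
    .bePack(0L, 4L))
}

#' Write a SangerRead as a minimal ABIF (.ab1) file
#'
#' Emits a spec-conformant ABIF container holding the basecalls (PBAS.1/2),
#' quality values (PCON.1/2), sample name (SMPL.1) and, when the read
#' carries them, the peak locations (PLOC.1/2) and the four trace channels
#' (DATA.9-12 in the channel order recorded in FWO_.1).  The result parses
#' back to an equal read with \code{\link{readABIF}} and is readable by
#' standard chromatogram software.
#'
#' @param read A valid \linkS4class{SangerRead}.
#' @param path Output path.
#' @return \code{path}, invisibly.
#' @export
writeABIF <- function(read, path) {
  stopifnot(is(read, "SangerRead"))
  validObject(read)

  tags <- list()
  addTag <- function(name, number, typeName, data, numElem) {
    type <- .ABIF_TYPE[[typeName]]
    elemSize <- c("1", "1", "2", "4", "1")[match(type, .ABIF_TYPE)]
    tags[[length(tags) + 1L]] <<- list(
      name = name, number = number, type = type,
      elemSize = as.integer(elemSize), numElem = numElem, data = data)
  }

  basesRaw <- charToRaw(read@bases)
  qvRaw <- as.raw(read@qualities)
  hasTraces <- nrow(read@traces) > 0L
  if (hasTraces) {
    fwo <- "ACGT"
    for (k in 1:4)
      addTag("DATA", 8L + k, "short",
             .bePackVec(read@traces[, substr(fwo, k, k)], 2L),
             nrow(read@traces))
    addTag("FWO_", 1L, "char", charToRaw(fwo), 4L)
  }
  addTag("PBAS", 1L, "char", basesRaw, length(basesRaw))
  addTag("PBAS", 2L, "char", basesRaw, length(basesRaw))
  addTag("PCON", 1L, "char", qvRaw, length(qvRaw))
  addTag("PCON", 2L, "char", qvRaw, length(qvRaw))
  if (length(read@peakLocations)) {
    plocRaw <- .bePackVec(read@peakLocations, 2L)
    addTag("PLOC", 1L, "short", plocRaw, length(read@peakLocations))
    addTag("PLOC", 2L, "short", plocRaw, length(read@peakLocations))
  }
  smplRaw <- charToRaw(read@sampleId)
  addTag("SMPL", 1L, "pString", c(as.raw(length(smplRaw)), smplRaw),
         length(smplRaw) + 1L)

  # layout: 128-byte header | data blocks (>4 bytes only) | directory
  offset <- 128L
  blocks <- list()
  for (i in seq_along(tags)) {
    if (length(tags[[i]]$data) > 4L) {
      tags[[i]]$offset <- offset
      blocks[[length(blocks) + 1L]] <- tags[[i]]$data
      offset <- offset + length(tags[[i]]$data)
    } else tags[[i]]$offset <- 0L
  }
  dirOffset <- offset
  dirRaw <- do.call(c, lapply(tags, function(t)
    .abifEntryRaw(t$name, t$number, t$type, t$elemSize, t$numElem,
                  t$data, t$offset)))

  tdir <- c(charToRaw("tdir"), .bePack(1L, 4L), .bePack(1023L, 2L),
            .bePack(28L, 2L), .bePack(length(tags), 4L),
            .bePack(28L * length(tags), 4L), .bePack(dirOffset, 4L),
            .bePack(0L, 4L))
  header <- c(charToRaw("ABIF"), .bePack(101L, 2L), tdir)
  header <- c(header, raw(128L - length(header)))

  out <- c(header, if (length(blocks)) do.call(c, blocks) else raw(0), dirRaw)
  con <- tryCatch(file(path, "wb"),
                  error = function(e) stop("cannot open for writing: ", path))
  on.exit(close(con))
  writeBin(out, con)
  invisible(path)
}
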