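# Event-table I/O.
#
# The on-disk format is a minimal TSV dialect: UTF-8, '.' decimal separator,
# fixed header `track_id x_nm y_nm z_nm kind edep_eV`, kind in {ION, EXC},
# one inelastic event per row.  Coordinates and energies are written with a
# full decimal representation so that write -> read round-trips bit-exactly.

EVENT_HEADER <- c("track_id", "x_nm", "y_nm", "z_nm", "kind", "edep_eV")

#' Read an event table
#'
#' Reads a TSV event table into an [EventSet-class].  Rows are validated:
#' events depositing less than 1 eV lie below the electron transport
#' cut-off and are rejected, as are unknown `kind` tokens, non-finite
#' coordinates and malformed rows (errors name the offending line).
#'
#' @param path path to the event table.
#' @param dialect format name; only `"tsv"` is defined.
#' @return An [EventSet-class].
#' @seealso [writeEvents()]
#' @export
readEvents <- function(path, dialect = "tsv") {
  dialect <- match.arg(dialect, "tsv")
  if (!file.exists(path)) stop("event table not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) stop("empty file (missing header): ", path)
  hdr <- strsplit(lines[[1]], "\t", fixed = TRUE)[[1]]
  if (!identical(hdr, EVENT_HEADER))
    stop("bad header: expected '", paste(EVENT_HEADER, collapse = "\\t"), "'")
  n <- length(lines) - 1L
  if (n == 0) return(EventSet())
  fields <- strsplit(lines[-1], "\t", fixed = TRUE)
  bad <- which(lengths(fields) != length(EVENT_HEADER))
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": expected ",
         length(EVENT_HEADER), " fields, got ", lengths(fields)[bad[1]])
  m <- matrix(unlist(fields), ncol = length(EVENT_HEADER), byrow = TRUE)
  suppressWarnings({
    track_id <- as.integer(m[, 1])
    xyz <- matrix(as.numeric(m[, 2:4]), ncol = 3)
    edep <- as.numeric(m[, 6])
  })
  kind <- m[, 5]
  bad <- which(is.na(track_id) | is.na(edep) | rowSums(is.na(xyz)) > 0)
  if (length(bad))
    stop("malformed row at line ", bad[1] + 1L, ": non-numeric field")
  bad <- which(!is.finite(xyz[, 1]) | !is.finite(xyz[, 2]) | !is.finite(xyz[, 3]))
  if (length(bad))
    stop("invalid row at line ", bad[1] + 1L, ": non-finite coordinate")
  bad <- which(!(kind %in% c("ION", "EXC")))
  if (length(bad))
    stop("invalid row at line ", bad[1] + 1L, ": unknown kind '",
         kind[bad[1]], "' (expected ION or EXC)")
  bad <- which(edep < EDEP_CUTOFF_EV)
  if (length(bad))
    stop("invalid row at line ", bad[1] + 1L, ": edep_eV = ", edep[bad[1]],
         " below the ", EDEP_CUTOFF_EV, " eV transport cut-off")
  EventSet(data.frame(track_id = track_id, x_nm = xyz[, 1], y_nm = xyz[, 2],
                      z_nm = xyz[, 3], kind = kind, edep_eV = edep,
                      stringsAsFactors = FALSE))
}

#' Write an event table
#'
#' Writes an [EventSet-class] to the TSV event-table format.  Numeric
#' fields use a 17-significant-digit decimal representation, so
#' `readEvents(writeEvents(es))` reproduces `es` bit-exactly.
#'
#' @param es an [EventSet-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeEvents <- function(es, path) {
  stopifnot(is(es, "EventSet"))
  validObject(es)
  ev <- es@events
  con <- file(path, "w", encoding = "UTF-8")
  on.exit(close(con))
  writeLines(paste(EVENT_HEADER, collapse = "\t"), con)
  if (nrow(ev) > 0) {
    num <- function(v) sprintf("%.17g", v)
    writeLines(paste(ev$track_id, num(ev$x_nm), num(ev$y_nm), num(ev$z_nm),
                     ev$kind, num(ev$edep_eV), sep = "\t"), con)
  }
  invisible(path)
}
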