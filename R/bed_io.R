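#' Read a BED4 interval file
#'
#' Reads tab-separated BED lines (`chrom`, `start`, `stop`, `name`); columns
#' beyond the fourth are ignored. Header lines starting with `track`,
#' `browser` or `#` are skipped. Intervals are returned in file order, never
#' reordered or deduplicated. Coordinates are BED-style: 0-based, half-open.
#'
#' @param path Path to a BED file.
#' @return An interval data frame (`chrom`, `start`, `stop`, `label`). An
#'   empty file yields zero rows, not an error.
#' @seealso [write_bed()]
#' @export
read_bed <- function(path) {
  if (!file.exists(path)) stop("BED file not found: ", path, call. = FALSE)
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) {
    return(genomic_intervals(character(0), numeric(0), numeric(0), character(0)))
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  bad <- which(nf < 4L)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": fewer than 4 tab-separated fields", call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  start_s <- vapply(parts, `[[`, "", 2L)
  stop_s <- vapply(parts, `[[`, "", 3L)
  label <- vapply(parts, `[[`, "", 4L)
  bad <- which(!grepl("^[0-9]+$", start_s) | !grepl("^[0-9]+$", stop_s))
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": non-integer coordinates", call. = FALSE)
  }
  start <- as.numeric(start_s)
  stp <- as.numeric(stop_s)
  bad <- which(start >= stp)
  if (length(bad)) {
    stop("malformed BED line ", lineno[bad[1]], " in ", path,
         ": start >= stop", call. = FALSE)
  }
  check_intervals(
    data.frame(chrom = chrom, start = start, stop = stp, label = label,
               stringsAsFactors = FALSE),
    what = paste0("BED file ", path)
  )
}

#' Write intervals as a BED4 file
#'
#' Emits four tab-separated columns. `read_bed(write_bed(x, f))` reproduces
#' `x` exactly (chrom, start, stop, label).
#'
#' @param intervals A valid interval data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_bed <- function(intervals, path) {
  intervals <- check_intervals(intervals)
  lines <- if (nrow(intervals) == 0L) character(0) else {
    paste(intervals$chrom,
          format(intervals$start, scientific = FALSE, trim = TRUE),
          format(intervals$stop, scientific = FALSE, trim = TRUE),
          intervals$label,
          sep = "\t")
  }
  ok <- tryCatch({ writeLines(lines, path); TRUE },
                 error = function(e) stop("cannot write BED file ", path, ": ",
                                          conditionMessage(e), call. = FALSE))
  invisible(path)
}

#' Read a file of genomic positions
#'
#' Two dialects are accepted: `"two-column"` (`chrom<TAB>pos`, one position
#' per line) and `"bed"` (width-1 BED intervals, `pos = start`; any interval
#' of width other than 1 is an error). Duplicates are preserved and order is
#' file order.
#'
#' @param path Path to the position file.
#' @param dialect `"two-column"` (default) or `"bed"`.
#' @return A position data frame (`chrom`, `pos`).
#' @export
read_positions <- function(path, dialect = c("two-column", "bed")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("position file not found: ", path, call. = FALSE)
  if (dialect == "bed") {
    iv <- read_bed(path)
    bad <- which(iv$stop - iv$start != 1)
    if (length(bad)) {
      stop("position BED file ", path, ": interval at data row ", bad[1],
           " has width != 1", call. = FALSE)
    }
    return(genomic_positions(iv$chrom, iv$start))
  }
  lines <- readLines(path, warn = FALSE)
  keep <- !grepl("^(track|browser|#)", lines)
  lines <- lines[keep]
  lineno <- which(keep)
  if (length(lines) == 0L) return(genomic_positions(character(0), numeric(0)))
  parts <- strsplit(lines, "\t", fixed = TRUE)
  bad <- which(lengths(parts) < 2L)
  if (length(bad)) {
    stop("malformed position line ", lineno[bad[1]], " in ", path,
         ": expected chrom<TAB>pos", call. = FALSE)
  }
  chrom <- vapply(parts, `[[`, "", 1L)
  pos_s <- vapply(parts, `[[`, "", 2L)
  bad <- which(!grepl("^[0-9]+$", pos_s))
  if (length(bad)) {
    stop("malformed position line ", lineno[bad[1]], " in ", path,
         ": non-integer position", call. = FALSE)
  }
  genomic_positions(chrom, as.numeric(pos_s))
}

#' Write genomic positions as a two-column TSV
#'
#' @param positions A position data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_positions <- function(positions, path) {
  positions <- check_positions(positions)
  lines <- if (nrow(positions) == 0L) character(0) else {
    paste(positions$chrom,
          format(positions$pos, scientific = FALSE, trim = TRUE), sep = "\t")
  }
  writeLines(lines, path)
  invisible(path)
}
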