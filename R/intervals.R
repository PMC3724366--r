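#' Construct a set of genomic intervals
#'
#' Genomic intervals are the unit of BED input/output and of index
#' construction. Coordinates follow the BED convention throughout the package:
#' 0-based, half-open `[start, stop)`. Empty intervals (`start >= stop`) are
#' rejected rather than silently repaired.
#'
#' @param chrom Character vector of chromosome names (non-empty, no
#'   whitespace).
#' @param start Integer-valued start coordinates, `>= 0` (0-based, inclusive).
#' @param stop Integer-valued stop coordinates (exclusive); must exceed
#'   `start`.
#' @param label Character vector of annotation labels. Labels need not be
#'   unique: identity inside an index is the numeric id assigned at load, not
#'   the label.
#' @return A `data.frame` with columns `chrom`, `start`, `stop`, `label`.
#' @examples
#' genomic_intervals("chr1", c(10, 30), c(20, 45), c("a", "b"))
#' @export
genomic_intervals <- function(chrom, start, stop, label) {
  df <- data.frame(
    chrom = as.character(chrom),
    start = as.numeric(start),
    stop = as.numeric(stop),
    label = as.character(label),
    stringsAsFactors = FALSE
  )
  check_intervals(df)
}

#' Construct a set of genomic positions
#'
#' Single base-pair positions (0-based) to be annotated against an interval
#' index. A position `p` is treated as the width-1 interval `[p, p + 1)` in
#' all queries.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer-valued positions, `>= 0`.
#' @return A `data.frame` with columns `chrom`, `pos`.
#' @export
genomic_positions <- function(chrom, pos) {
  df <- data.frame(chrom = as.character(chrom), pos = as.numeric(pos),
                   stringsAsFactors = FALSE)
  check_positions(df)
}

# Validate (and lightly normalize) an interval data frame. Returns the frame;
# stops with a row-indexed message on the first violation.
check_intervals <- function(x, what = "intervals") {
  if (!is.data.frame(x)) {
    stop(what, " must be a data.frame with columns chrom, start, stop, label",
         call. = FALSE)
  }
  need <- c("chrom", "start", "stop", "label")
  miss <- setdiff(need, names(x))
  if (length(miss)) {
    stop(what, " is missing column(s): ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  x <- x[need]
  x$chrom <- as.character(x$chrom)
  x$label <- as.character(x$label)
  x$start <- as.numeric(x$start)
  x$stop <- as.numeric(x$stop)
  if (nrow(x) == 0L) return(x)
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) | grepl("[[:space:]]", x$chrom))
  if (length(bad)) {
    stop(what, ": invalid chromosome name at row ", bad[1], call. = FALSE)
  }
  bad <- which(is.na(x$start) | is.na(x$stop) |
                 x$start != floor(x$start) | x$stop != floor(x$stop))
  if (length(bad)) {
    stop(what, ": non-integer coordinates at row ", bad[1], call. = FALSE)
  }
  bad <- which(x$start < 0)
  if (length(bad)) {
    stop(what, ": negative start at row ", bad[1], call. = FALSE)
  }
  bad <- which(x$start >= x$stop)
  if (length(bad)) {
    stop(what, ": start >= stop at row ", bad[1],
         " (empty intervals are rejected)", call. = FALSE)
  }
  bad <- which(is.na(x$label) | grepl("[\t\n\r]", x$label))
  if (length(bad)) {
    stop(what, ": label missing or containing tab/newline at row ", bad[1],
         call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

check_positions <- function(x, what = "positions") {
  if (!is.data.frame(x) || !all(c("chrom", "pos") %in% names(x))) {
    stop(what, " must be a data.frame with columns chrom, pos", call. = FALSE)
  }
  x <- x[c("chrom", "pos")]
  x$chrom <- as.character(x$chrom)
  x$pos <- as.numeric(x$pos)
  if (nrow(x) == 0L) return(x)
  bad <- which(is.na(x$chrom) | !nzchar(x$chrom) | grepl("[[:space:]]", x$chrom))
  if (length(bad)) stop(what, ": invalid chromosome at row ", bad[1], call. = FALSE)
  bad <- which(is.na(x$pos) | x$pos != floor(x$pos) | x$pos < 0)
  if (length(bad)) {
    stop(what, ": position must be a non-negative integer (row ", bad[1], ")",
         call. = FALSE)
  }
  rownames(x) <- NULL
  x
}

#' Sort intervals into index construction order
#'
#' Chromosomes are ordered lexicographically (C locale); within a chromosome,
#' intervals are ordered by start ascending, then stop *descending*, then
#' label ascending. The stop-descending tie-break guarantees that when two
#' intervals share a start, the containing interval precedes the contained
#' one, which the single-pass construction in [nclist_build()] relies on.
#'
#' @param intervals A valid interval data frame (see [genomic_intervals()]).
#' @return The same rows, reordered.
#' @export
sort_intervals <- function(intervals) {
  intervals <- check_intervals(intervals)
  if (nrow(intervals) == 0L) return(intervals)
  o <- order(intervals$chrom, intervals$start, -intervals$stop,
             intervals$label, method = "radix")
  out <- intervals[o, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Strict interval containment
#'
#' `outer` contains `inner` when `outer$start <= inner$start` and
#' `inner$stop <= outer$stop` and the two coordinate pairs are not identical.
#' Coordinate-identical intervals are siblings, never parent and child: mutual
#' containment would make the parent choice arbitrary and break the tree.
#'
#' @param outer,inner Single intervals: one-row data frames or lists with
#'   `chrom`, `start`, `stop`.
#' @return `TRUE` or `FALSE`.
#' @export
interval_contains <- function(outer, inner) {
  oc <- as.character(outer$chrom[1]); ic <- as.character(inner$chrom[1])
  if (!identical(oc, ic)) {
    stop("interval_contains: intervals are on different chromosomes (",
         oc, " vs ", ic, ")", call. = FALSE)
  }
  os <- as.numeric(outer$start[1]); oe <- as.numeric(outer$stop[1])
  is_ <- as.numeric(inner$start[1]); ie <- as.numeric(inner$stop[1])
  os <= is_ && ie <= oe && !(os == is_ && oe == ie)
}

# Vectorised strict containment of (is, ie) in (os, oe); same chromosome
# assumed by the caller.
.contains_vec <- function(os, oe, is_, ie) {
  os <= is_ & ie <= oe & !(os == is_ & oe == ie)
}

# Run code under a fixed seed, restoring the caller's RNG state afterwards.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}
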