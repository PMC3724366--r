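# Lazily (re)build the per-(chromosome, sublist) query index: members sorted
# by start (stops are then non-decreasing, since sublists are containment
# free), with each member's child sublist resolved once. Any mutation of the
# store clears `store$idx`.
.refresh_index <- function(store) {
  if (!is.null(store$idx)) return(invisible(NULL))
  idx <- new.env(parent = emptyenv())
  n <- length(store$node_id)
  if (n > 0L) {
    key <- paste(store$node_chrom, store$node_sub, sep = "\r")
    grp <- split(seq_len(n), key)
    for (k in names(grp)) {
      rows <- grp[[k]]
      o <- order(store$node_start[rows], store$node_stop[rows],
                 store$node_id[rows], method = "radix")
      rows <- rows[o]
      ids <- store$node_id[rows]
      child <- vapply(as.character(ids), function(s) {
        v <- store$edge_env[[s]]
        if (is.null(v)) NA_real_ else v
      }, numeric(1), USE.NAMES = FALSE)
      idx[[k]] <- list(id = ids, start = store$node_start[rows],
                       stop = store$node_stop[rows],
                       label = store$node_label[rows], child = child)
    }
  }
  store$idx <- idx
  invisible(NULL)
}

# Core recursive (iteratively scheduled) overlap search. Returns raw vectors
# plus operation counts; the exported wrappers shape the output.
.nc_query_raw <- function(store, chrom, q_start, q_stop) {
  .refresh_index(store)
  idx <- store$idx
  nodes_ex <- 0L
  subs_in <- 0L
  hid <- numeric(0); hstart <- numeric(0); hstop <- numeric(0)
  hlabel <- character(0)
  pend <- paste(chrom, 0, sep = "\r")
  while (length(pend)) {
    sl <- idx[[pend[1L]]]
    pend <- pend[-1L]
    if (is.null(sl)) next
    subs_in <- subs_in + 1L
    L <- length(sl$stop)
    # binary search: first member whose stop exceeds q_start
    lo <- 1L; hi <- L
    while (lo <= hi) {
      mid <- (lo + hi) %/% 2L
      nodes_ex <- nodes_ex + 1L
      if (sl$stop[mid] > q_start) hi <- mid - 1L else lo <- mid + 1L
    }
    i <- lo
    while (i <= L && sl$start[i] < q_stop) {
      nodes_ex <- nodes_ex + 1L
      hid <- c(hid, sl$id[i]); hstart <- c(hstart, sl$start[i])
      hstop <- c(hstop, sl$stop[i]); hlabel <- c(hlabel, sl$label[i])
      if (!is.na(sl$child[i])) pend <- c(pend, paste(chrom, sl$child[i], sep = "\r"))
      i <- i + 1L
    }
    if (i <= L) nodes_ex <- nodes_ex + 1L  # member whose start ended the scan
  }
  if (length(hid) > 1L) {
    o <- order(hstart, -hstop, hid, method = "radix")
    hid <- hid[o]; hstart <- hstart[o]; hstop <- hstop[o]; hlabel <- hlabel[o]
  }
  list(id = hid, start = hstart, stop = hstop, label = hlabel,
       nodes_examined = nodes_ex, sublists_entered = subs_in)
}

#' Range overlap query
#'
#' Returns every stored interval on `chrom` whose half-open range overlaps
#' `[q_start, q_stop)` — strict inequalities, so a hit satisfies
#' `start < q_stop` and `stop > q_start`. Per sublist the search binary
#' searches the (sorted) stop values for the first member ending after
#' `q_start`, scans forward while starts precede `q_stop`, and recurses into
#' each hit's child sublist. Hits are ordered by (start asc, stop desc, id
#' asc). A chromosome absent from the store yields an empty result, not an
#' error.
#'
#' The result carries two instrumentation attributes: `nodes_examined` (node
#' records inspected, counting binary-search probes and scanned members) and
#' `sublists_entered`.
#'
#' @param store An `nclist` store.
#' @param chrom Chromosome name.
#' @param q_start,q_stop Half-open query range, `q_start < q_stop`.
#' @return A data frame of hits: `id`, `chrom`, `start`, `stop`, `label`.
#' @export
nclist_query <- function(store, chrom, q_start, q_stop) {
  stopifnot(inherits(store, "nclist"))
  q_start <- as.numeric(q_start); q_stop <- as.numeric(q_stop)
  if (is.na(q_start) || is.na(q_stop) || q_start >= q_stop) {
    stop("query range must satisfy q_start < q_stop", call. = FALSE)
  }
  raw <- .nc_query_raw(store, as.character(chrom), q_start, q_stop)
  out <- data.frame(id = raw$id,
                    chrom = rep(as.character(chrom), length(raw$id)),
                    start = raw$start, stop = raw$stop, label = raw$label,
                    stringsAsFactors = FALSE)
  attr(out, "nodes_examined") <- raw$nodes_examined
  attr(out, "sublists_entered") <- raw$sublists_entered
  out
}

#' Point overlap query
#'
#' A position `pos` is queried as the width-1 range `[pos, pos + 1)`. Under
#' the half-open convention a position equal to an interval's `stop`
#' coordinate is therefore *not* covered by it; callers holding 1-based
#' inclusive positions should subtract one first (the command line interface
#' exposes `--one-based` for this).
#'
#' @param store An `nclist` store.
#' @param chrom Chromosome name.
#' @param pos 0-based position, `>= 0`.
#' @return As [nclist_query()].
#' @export
nclist_query_point <- function(store, chrom, pos) {
  pos <- as.numeric(pos)
  if (is.na(pos) || pos < 0) stop("pos must be >= 0", call. = FALSE)
  nclist_query(store, chrom, pos, pos + 1)
}

#' Annotate a set of positions against a store
#'
#' Batch overlap join: one output row per (position, overlapping interval)
#' pair, in input position order then hit order. Positions overlapping
#' nothing emit a single row with label `"."` (BED's null marker) and missing
#' feature fields, so every input position appears in the output.
#'
#' @param store An `nclist` store.
#' @param positions A position data frame (`chrom`, `pos`).
#' @return A data frame with columns `chrom`, `pos`, `label`,
#'   `feature_start`, `feature_stop`, `feature_id`.
#' @export
annotate_positions <- function(store, positions) {
  stopifnot(inherits(store, "nclist"))
  positions <- check_positions(positions)
  n <- nrow(positions)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    raw <- .nc_query_raw(store, positions$chrom[i], positions$pos[i],
                         positions$pos[i] + 1)
    k <- length(raw$id)
    out[[i]] <- if (k == 0L) {
      list(chrom = positions$chrom[i], pos = positions$pos[i], label = ".",
           feature_start = NA_real_, feature_stop = NA_real_,
           feature_id = NA_real_)
    } else {
      list(chrom = rep(positions$chrom[i], k), pos = rep(positions$pos[i], k),
           label = raw$label, feature_start = raw$start,
           feature_stop = raw$stop, feature_id = raw$id)
    }
  }
  data.frame(
    chrom = unlist(lapply(out, `[[`, "chrom")),
    pos = unlist(lapply(out, `[[`, "pos")),
    label = unlist(lapply(out, `[[`, "label")),
    feature_start = unlist(lapply(out, `[[`, "feature_start")),
    feature_stop = unlist(lapply(out, `[[`, "feature_stop")),
    feature_id = unlist(lapply(out, `[[`, "feature_id")),
    stringsAsFactors = FALSE
  )
}

#' Write an annotation table as TSV
#'
#' Missing feature fields are written as `"."` following BED conventions.
#'
#' @param annotations Output of [annotate_positions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annotations, path) {
  fmt <- function(x) {
    out <- format(x, scientific = FALSE, trim = TRUE)
    out[is.na(x)] <- "."
    out
  }
  lines <- c("chrom\tpos\tlabel\tfeature_start\tfeature_stop\tfeature_id")
  if (nrow(annotations) > 0L) {
    lines <- c(lines, paste(annotations$chrom, fmt(annotations$pos),
                            annotations$label, fmt(annotations$feature_start),
                            fmt(annotations$feature_stop),
                            fmt(annotations$feature_id), sep = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

#' Brute-force overlap scan (test oracle)
#'
#' Linear scan of every interval testing `start < q_stop && stop > q_start`
#' on the requested chromosome: the ground truth against which the indexed
#' query is checked.
#'
#' @param intervals An interval data frame.
#' @param chrom Chromosome name.
#' @param q_start,q_stop Half-open query range.
#' @return The overlapping rows of `intervals`, in input order.
#' @export
brute_force_overlap <- function(intervals, chrom, q_start, q_stop) {
  intervals <- check_intervals(intervals)
  hit <- intervals$chrom == as.character(chrom) &
    intervals$start < q_stop & intervals$stop > q_start
  out <- intervals[hit, , drop = FALSE]
  rownames(out) <- NULL
  out
}
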