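# Parent selection: among the candidate containers of an interval, the
# *minimal* containers are those that do not strictly contain another
# candidate (i.e. the innermost ones). Nested chains therefore always resolve
# to the innermost enclosing interval; only partially overlapping candidates
# leave a genuine choice, which the parent rule settles: "first" picks the
# earliest minimal container in construction sort order (start asc, stop desc,
# label asc), "last" the latest.
.pick_minimal <- function(cst, csp, rule) {
  k <- length(cst)
  if (k == 1L) return(1L)
  nonmin <- logical(k)
  for (j in seq_len(k)) {
    nonmin[j] <- any(cst >= cst[j] & csp <= csp[j] & !(cst == cst[j] & csp == csp[j]))
  }
  m <- which(!nonmin)
  if (rule == "first") m[1L] else m[length(m)]
}

#' Build a nested containment list from an interval set
#'
#' Intervals are sorted with [sort_intervals()] and walked once per
#' chromosome. An active list of potentially enclosing intervals is
#' maintained; each interval is attached to the parent chosen by
#' `parent_rule` among its minimal (innermost) containers, receiving that
#' parent's child sublist value (a fresh sublist and an edge are created the
#' first time a parent acquires a child). Intervals contained by nothing form
#' sublist 0, the per-chromosome root. Ids are assigned in sorted order
#' starting at 1; sublist values come from a monotone counter starting at 1.
#'
#' @param intervals A valid interval data frame.
#' @param parent_rule `"first"` (default) or `"last"`: which parent an
#'   interval contained by several partially overlapping candidates is
#'   assigned to, in construction sort order.
#' @return An `nclist` store satisfying all structural invariants.
#' @examples
#' iv <- genomic_intervals("chr1", c(0, 10, 12), c(100, 20, 15), c("a", "b", "c"))
#' st <- nclist_build(iv)
#' node_table(st)
#' @export
nclist_build <- function(intervals, parent_rule = c("first", "last")) {
  parent_rule <- match.arg(parent_rule)
  s <- sort_intervals(intervals)
  n <- nrow(s)
  store <- new_store(parent_rule)
  if (n == 0L) return(store)

  st_start <- s$start
  st_stop <- s$stop
  node_sub <- numeric(n)
  next_sub <- 1
  edge_p <- numeric(0)
  edge_s <- numeric(0)

  chrom_rle <- rle(s$chrom)
  pos <- 1L
  for (ci in seq_along(chrom_rle$lengths)) {
    rows <- pos:(pos + chrom_rle$lengths[ci] - 1L)
    pos <- pos + chrom_rle$lengths[ci]
    act <- integer(0)                      # active rows, construction order
    child_sub <- new.env(parent = emptyenv())
    for (i in rows) {
      qs <- st_start[i]; qe <- st_stop[i]
      if (length(act)) act <- act[st_stop[act] > qs]
      parent <- 0L
      if (length(act)) {
        cm <- st_stop[act] >= qe & !(st_start[act] == qs & st_stop[act] == qe)
        cand <- act[cm]
        if (length(cand)) {
          parent <- cand[.pick_minimal(st_start[cand], st_stop[cand], parent_rule)]
        }
      }
      if (parent == 0L) {
        node_sub[i] <- 0
      } else {
        k <- as.character(parent)
        sb <- child_sub[[k]]
        if (is.null(sb)) {
          sb <- next_sub
          next_sub <- next_sub + 1
          child_sub[[k]] <- sb
          edge_p <- c(edge_p, parent)
          edge_s <- c(edge_s, sb)
        }
        node_sub[i] <- sb
      }
      act <- c(act, i)
    }
  }

  store$node_id <- as.numeric(seq_len(n))
  store$node_chrom <- s$chrom
  store$node_start <- st_start
  store$node_stop <- st_stop
  store$node_sub <- node_sub
  store$node_label <- s$label
  store$next_id <- n + 1
  store$next_sub <- next_sub
  for (i in seq_along(edge_p)) .add_edge(store, edge_p[i], edge_s[i])
  store
}

#' Exhaustive containment-forest oracle
#'
#' Independent quadratic reference for [nclist_build()]'s parent assignment:
#' for every interval it finds all strict containers by pairwise comparison,
#' keeps the minimal ones (those containing no other container) and applies
#' `parent_rule`. Intended for testing on small inputs only.
#'
#' @param intervals A valid interval data frame.
#' @param parent_rule `"first"` or `"last"` (see [nclist_build()]).
#' @return A data frame in construction sort order with the interval columns
#'   plus `id` (1-based position in sorted order) and `parent` (the id of the
#'   assigned parent, 0 for root intervals).
#' @export
containment_forest_oracle <- function(intervals, parent_rule = c("first", "last")) {
  parent_rule <- match.arg(parent_rule)
  s <- sort_intervals(intervals)
  n <- nrow(s)
  if (n > 10000L) stop("oracle is quadratic; refusing n > 10000", call. = FALSE)
  parent <- numeric(n)
  for (i in seq_len(n)) {
    cand <- which(s$chrom == s$chrom[i] &
                    .contains_vec(s$start, s$stop, s$start[i], s$stop[i]))
    cand <- setdiff(cand, i)
    if (length(cand)) {
      parent[i] <- cand[.pick_minimal(s$start[cand], s$stop[cand], parent_rule)]
    }
  }
  cbind(s, id = as.numeric(seq_len(n)), parent = parent)
}

# Parent id of every node (0 = root), ordered by node id. For build() output,
# directly comparable with the oracle's `parent` column.
store_parent_map <- function(store) {
  n <- length(store$node_id)
  parent <- numeric(n)
  if (n == 0L) return(parent)
  for (i in seq_len(n)) {
    s <- store$node_sub[i]
    if (s != 0) {
      p <- store$sub_parent_env[[as.character(s)]]
      parent[i] <- if (is.null(p)) NA_real_ else p
    }
  }
  parent[order(store$node_id)]
}
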