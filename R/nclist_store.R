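# The NCList store is an environment holding the three relational tables of
# the index as parallel vectors (node: id/chrom/start/stop/sub + label, i.e.
# the masterkey; edge: parent id -> child sublist), two O(1) edge lookup
# environments, monotone id/sub counters, the parent-selection rule and a
# lazily (re)built per-(chrom, sublist) dual-sorted query index. Environments
# give reference semantics: inserts and deletes mutate the store in place,
# mirroring the in-place update design of the relational representation.

new_store <- function(parent_rule = "first") {
  st <- new.env(parent = emptyenv())
  st$node_id <- numeric(0)
  st$node_chrom <- character(0)
  st$node_start <- numeric(0)
  st$node_stop <- numeric(0)
  st$node_sub <- numeric(0)
  st$node_label <- character(0)
  st$edge_env <- new.env(parent = emptyenv())      # parent id -> child sub
  st$sub_parent_env <- new.env(parent = emptyenv()) # child sub -> parent id
  st$next_id <- 1
  st$next_sub <- 1
  st$parent_rule <- parent_rule
  st$idx <- NULL
  class(st) <- "nclist"
  st
}

.add_edge <- function(store, parent_id, child_sub) {
  parent_id <- as.numeric(parent_id)
  child_sub <- as.numeric(child_sub)
  store$edge_env[[as.character(parent_id)]] <- child_sub
  store$sub_parent_env[[as.character(child_sub)]] <- parent_id
}

.drop_edge_by_parent <- function(store, parent_id) {
  k <- as.character(parent_id)
  s <- store$edge_env[[k]]
  if (!is.null(s)) {
    rm(list = k, envir = store$edge_env)
    sk <- as.character(s)
    if (!is.null(store$sub_parent_env[[sk]])) rm(list = sk, envir = store$sub_parent_env)
  }
  invisible(s)
}

.drop_edge_by_sub <- function(store, child_sub) {
  sk <- as.character(child_sub)
  p <- store$sub_parent_env[[sk]]
  if (!is.null(p)) {
    rm(list = sk, envir = store$sub_parent_env)
    pk <- as.character(p)
    if (!is.null(store$edge_env[[pk]])) rm(list = pk, envir = store$edge_env)
  }
  invisible(p)
}

.child_sub_of <- function(store, parent_id) {
  store$edge_env[[as.character(parent_id)]]
}

#' @export
print.nclist <- function(x, ...) {
  n <- length(x$node_id)
  cat("<nclist> ", n, " interval(s), ",
      length(ls(x$edge_env)), " edge(s), ",
      length(unique(x$node_chrom)), " chromosome(s), parent rule: ",
      x$parent_rule, "\n", sep = "")
  if (n > 0) {
    cat("  max nesting depth: ", nclist_depth(x), "\n", sep = "")
  }
  invisible(x)
}

#' Number of intervals in an NCList store
#' @param x An `nclist` store.
#' @param ... Ignored.
#' @return Integer count of stored intervals.
#' @export
length.nclist <- function(x) length(x$node_id)

#' Extract the node table of a store
#'
#' One row per stored interval: `id`, `chrom`, `start`, `stop`, `sub` (the
#' sublist the interval belongs to; sublist 0 is the per-chromosome root).
#'
#' @param store An `nclist` store.
#' @return A data frame ordered by `id`.
#' @export
node_table <- function(store) {
  stopifnot(inherits(store, "nclist"))
  o <- order(store$node_id)
  data.frame(id = store$node_id[o], chrom = store$node_chrom[o],
             start = store$node_start[o], stop = store$node_stop[o],
             sub = store$node_sub[o], stringsAsFactors = FALSE)
}

#' Extract the edge table of a store
#'
#' One row per parent interval that has nested children: `parent_id`,
#' `child_sub` (the sublist holding everything that parent completely
#' contains).
#'
#' @param store An `nclist` store.
#' @return A data frame ordered by `parent_id`.
#' @export
edge_table <- function(store) {
  stopifnot(inherits(store, "nclist"))
  ks <- ls(store$edge_env)
  if (length(ks) == 0L) {
    return(data.frame(parent_id = numeric(0), child_sub = numeric(0)))
  }
  p <- as.numeric(ks)
  s <- unname(vapply(ks, function(k) store$edge_env[[k]], numeric(1)))
  o <- order(p)
  data.frame(parent_id = p[o], child_sub = s[o], stringsAsFactors = FALSE)
}

#' Extract the masterkey table of a store
#'
#' The numeric-id-to-label mapping for every stored interval.
#'
#' @param store An `nclist` store.
#' @return A data frame (`id`, `label`) ordered by `id`.
#' @export
masterkey_table <- function(store) {
  stopifnot(inherits(store, "nclist"))
  o <- order(store$node_id)
  data.frame(id = store$node_id[o], label = store$node_label[o],
             stringsAsFactors = FALSE)
}

#' Recover the stored intervals
#'
#' @param store An `nclist` store.
#' @return An interval data frame (one row per node, ordered by id) with an
#'   extra `id` column.
#' @export
store_intervals <- function(store) {
  stopifnot(inherits(store, "nclist"))
  o <- order(store$node_id)
  data.frame(chrom = store$node_chrom[o], start = store$node_start[o],
             stop = store$node_stop[o], label = store$node_label[o],
             id = store$node_id[o], stringsAsFactors = FALSE)
}

#' Maximum nesting depth of a store
#'
#' Root intervals are at depth 1; each sublist level adds one.
#'
#' @param store An `nclist` store.
#' @return Integer depth (0 for an empty store).
#' @export
nclist_depth <- function(store) {
  stopifnot(inherits(store, "nclist"))
  if (length(store$node_id) == 0L) return(0L)
  depth_memo <- new.env(parent = emptyenv())
  sub_depth <- function(s) {
    if (s == 0) return(1L)
    k <- as.character(s)
    d <- depth_memo[[k]]
    if (!is.null(d)) return(d)
    p <- store$sub_parent_env[[k]]
    if (is.null(p)) return(NA_integer_)  # orphan; validator reports it
    pr <- match(p, store$node_id)
    d <- sub_depth(store$node_sub[pr]) + 1L
    depth_memo[[k]] <- d
    d
  }
  max(vapply(unique(store$node_sub), sub_depth, integer(1)))
}

# Deep copy of a store (environments are reference objects).
store_clone <- function(store) {
  st <- new_store(store$parent_rule)
  for (f in c("node_id", "node_chrom", "node_start", "node_stop", "node_sub",
              "node_label", "next_id", "next_sub")) {
    st[[f]] <- store[[f]]
  }
  for (k in ls(store$edge_env)) st$edge_env[[k]] <- store$edge_env[[k]]
  for (k in ls(store$sub_parent_env)) st$sub_parent_env[[k]] <- store$sub_parent_env[[k]]
  st
}

# All structural-invariant violations, as a character vector (empty = valid).
store_violations <- function(store) {
  v <- character(0)
  n <- length(store$node_id)
  lens <- c(length(store$node_chrom), length(store$node_start),
            length(store$node_stop), length(store$node_sub),
            length(store$node_label))
  if (any(lens != n)) return("internal: node table columns have unequal lengths")
  if (n == 0L) {
    if (length(ls(store$edge_env)) > 0L) v <- c(v, "edge table non-empty for empty store")
    return(v)
  }
  if (anyDuplicated(store$node_id)) v <- c(v, "duplicate node ids")
  if (any(is.na(store$node_sub)) || any(store$node_sub < 0)) {
    v <- c(v, "node with missing or negative sub value")
  }
  if (any(store$node_start >= store$node_stop)) v <- c(v, "node with start >= stop")
  if (any(is.na(store$node_label))) v <- c(v, "masterkey entry missing for a node")
  if (store$next_id <= max(store$node_id)) v <- c(v, "next_id not above max node id")
  if (store$next_sub <= max(store$node_sub)) v <- c(v, "next_sub not above max sub value")

  # sibling non-containment (implies dual sortedness) per (chrom, sub)
  key <- paste(store$node_chrom, store$node_sub, sep = "\r")
  grp <- split(seq_len(n), key)
  for (k in names(grp)) {
    rows <- grp[[k]]
    if (length(rows) < 2L) next
    # distinct (start, stop) pairs must have strictly increasing starts AND
    # stops once sorted: any tie or inversion is a containment among siblings
    pairs <- unique(complex(real = store$node_start[rows],
                            imaginary = store$node_stop[rows]))
    if (length(pairs) < 2L) next
    o <- order(Re(pairs), Im(pairs))
    s <- Re(pairs)[o]; e <- Im(pairs)[o]
    if (any(diff(s) <= 0) || any(diff(e) <= 0)) {
      v <- c(v, paste0("containment among siblings in sublist ", k))
    }
  }

  # edge consistency
  ek <- ls(store$edge_env)
  e_parent <- as.numeric(ek)
  e_sub <- vapply(ek, function(x) store$edge_env[[x]], numeric(1))
  if (anyDuplicated(e_sub)) v <- c(v, "two edges point to the same sublist")
  for (i in seq_along(e_parent)) {
    pr <- match(e_parent[i], store$node_id)
    if (is.na(pr)) { v <- c(v, paste0("edge from unknown parent ", e_parent[i])); next }
    mem <- which(store$node_chrom == store$node_chrom[pr] &
                   store$node_sub == e_sub[i])
    if (length(mem) == 0L) {
      v <- c(v, paste0("orphan edge: sublist ", e_sub[i], " has no members"))
      next
    }
    ok <- .contains_vec(store$node_start[pr], store$node_stop[pr],
                        store$node_start[mem], store$node_stop[mem])
    if (!all(ok)) {
      v <- c(v, paste0("parent ", e_parent[i],
                       " does not strictly contain all of sublist ", e_sub[i]))
    }
  }
  # reverse map consistency
  for (sk in ls(store$sub_parent_env)) {
    p <- store$sub_parent_env[[sk]]
    if (!identical(store$edge_env[[as.character(p)]], as.numeric(sk))) {
      v <- c(v, "edge lookup maps out of sync")
      break
    }
  }
  # every non-root sub present in nodes has exactly one incoming edge
  subs <- unique(store$node_sub[store$node_sub != 0])
  missing_edge <- setdiff(subs, e_sub)
  if (length(missing_edge)) {
    v <- c(v, paste0("sublist without incoming edge: ",
                     paste(missing_edge, collapse = ", ")))
  }
  # nodes of one sublist must sit on one chromosome (root excluded)
  for (s in subs) {
    ch <- unique(store$node_chrom[store$node_sub == s])
    if (length(ch) > 1L) v <- c(v, paste0("sublist ", s, " spans chromosomes"))
  }
  v
}

#' Validate an NCList store
#'
#' Checks every structural invariant of the index: dual sortedness (no
#' containment among sublist siblings), edge consistency (each non-root
#' sublist has exactly one incoming edge whose parent strictly contains every
#' member), masterkey coverage, absence of orphan sublists, and counter
#' sanity.
#'
#' @param store An `nclist` store.
#' @return `TRUE`, invisibly; stops with a message naming the first violated
#'   invariant otherwise.
#' @export
validate_nclist <- function(store) {
  stopifnot(inherits(store, "nclist"))
  v <- store_violations(store)
  if (length(v)) stop("invalid nclist store: ", v[1], call. = FALSE)
  invisible(TRUE)
}
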