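# Recursive placement primitive shared by insertion and by containment repair
# after deletion. Given a node already present in the node table, place it
# into sublist `sub_val` of its chromosome:
#   * if a member of that sublist strictly contains the node, descend into the
#     rule-selected minimal container's child sublist (creating it if absent);
#   * otherwise settle here and *capture*: members of the sublist strictly
#     contained in the node move beneath it — into its existing child sublist
#     (recursively, so captures of captures resolve) or into a fresh sublist
#     with a new edge when the node had no children.
# The five insertion conditions fall out: a root interval containing nothing
# (A) settles in sublist 0 with no capture; a root interval containing root
# intervals (B) captures them into a fresh sublist; a contained interval with
# children (C) settles in its parent's sublist and captures; a contained
# childless interval joins an existing sublist (D) or gets a fresh one with a
# parent edge (E) via the descent step.
.place_node <- function(store, nid, sub_val) {
  r <- match(nid, store$node_id)
  ch <- store$node_chrom[r]
  qs <- store$node_start[r]
  qe <- store$node_stop[r]
  mem <- which(store$node_chrom == ch & !is.na(store$node_sub) &
                 store$node_sub == sub_val & store$node_id != nid)
  if (length(mem)) {
    ms <- store$node_start[mem]; me <- store$node_stop[mem]
    cand <- mem[.contains_vec(ms, me, qs, qe)]
    if (length(cand)) {
      o <- order(store$node_start[cand], -store$node_stop[cand],
                 store$node_label[cand], store$node_id[cand], method = "radix")
      cand <- cand[o]
      q <- cand[.pick_minimal(store$node_start[cand], store$node_stop[cand],
                              store$parent_rule)]
      qid <- store$node_id[q]
      qsub <- .child_sub_of(store, qid)
      if (is.null(qsub)) {
        qsub <- store$next_sub
        store$next_sub <- qsub + 1
        .add_edge(store, qid, qsub)
      }
      return(.place_node(store, nid, qsub))
    }
  }
  store$node_sub[r] <- sub_val
  if (length(mem)) {
    cap <- mem[.contains_vec(qs, qe, store$node_start[mem], store$node_stop[mem])]
    if (length(cap)) {
      s_child <- .child_sub_of(store, nid)
      if (is.null(s_child)) {
        s2 <- store$next_sub
        store$next_sub <- s2 + 1
        .add_edge(store, nid, s2)
        store$node_sub[cap] <- s2
      } else {
        o <- order(store$node_start[cap], -store$node_stop[cap],
                   store$node_label[cap], store$node_id[cap], method = "radix")
        for (cid in store$node_id[cap][o]) .place_node(store, cid, s_child)
      }
    }
  }
  invisible(nid)
}

#' Insert an interval into an NCList store in place
#'
#' The interval is validated first (on error the store is untouched), then
#' placed by the case analysis over the node/edge tables: it joins the
#' sublist of its parent (the rule-selected minimal container), acquiring a
#' fresh sublist and edge when it is the parent's first child; any members of
#' that sublist it strictly contains are moved beneath it. Fresh sublist
#' values come from a monotone counter and are never recycled.
#'
#' @param store An `nclist` store (modified in place).
#' @param interval A single interval: one-row data frame or list with
#'   `chrom`, `start`, `stop`, `label`.
#' @return The new node's id, invisibly.
#' @export
nclist_insert <- function(store, interval) {
  stopifnot(inherits(store, "nclist"))
  iv <- check_intervals(as.data.frame(interval, stringsAsFactors = FALSE),
                        what = "interval")
  if (nrow(iv) != 1L) stop("nclist_insert takes exactly one interval", call. = FALSE)
  nid <- store$next_id
  store$next_id <- nid + 1
  store$node_id <- c(store$node_id, nid)
  store$node_chrom <- c(store$node_chrom, iv$chrom)
  store$node_start <- c(store$node_start, iv$start)
  store$node_stop <- c(store$node_stop, iv$stop)
  store$node_sub <- c(store$node_sub, NA_real_)
  store$node_label <- c(store$node_label, iv$label)
  .place_node(store, nid, 0)
  store$idx <- NULL
  invisible(nid)
}

#' Delete an interval from an NCList store in place
#'
#' Deletion is keyed by node id (labels and coordinates may be duplicated).
#' A childless node is simply removed; if it was the sole member of its
#' sublist, the edge from its parent is dropped. A node with children has its
#' children promoted into its own sublist (sublist 0 for a root node) and the
#' edge removed. Promotion can place a child beside a partially overlapping
#' former sibling of the deleted node that strictly contains it; such
#' children are re-attached beneath that container (containment repair) so
#' that sublists stay free of internal nesting.
#'
#' @param store An `nclist` store (modified in place).
#' @param id Node id to remove.
#' @return The removed interval (one-row data frame), invisibly.
#' @export
nclist_delete <- function(store, id) {
  stopifnot(inherits(store, "nclist"))
  r <- match(id, store$node_id)
  if (is.na(r)) stop("no node with id ", id, " in store", call. = FALSE)
  ch <- store$node_chrom[r]
  s_x <- store$node_sub[r]
  removed <- data.frame(chrom = ch, start = store$node_start[r],
                        stop = store$node_stop[r], label = store$node_label[r],
                        stringsAsFactors = FALSE)
  s_c <- .child_sub_of(store, id)
  promoted <- numeric(0)
  if (!is.null(s_c)) {
    prows <- which(store$node_chrom == ch & store$node_sub == s_c)
    promoted <- store$node_id[prows]
    store$node_sub[prows] <- s_x
    .drop_edge_by_parent(store, id)
  }
  keep <- -r
  store$node_id <- store$node_id[keep]
  store$node_chrom <- store$node_chrom[keep]
  store$node_start <- store$node_start[keep]
  store$node_stop <- store$node_stop[keep]
  store$node_sub <- store$node_sub[keep]
  store$node_label <- store$node_label[keep]
  if (s_x != 0 && !any(store$node_chrom == ch & store$node_sub == s_x)) {
    .drop_edge_by_sub(store, s_x)
  }
  if (length(promoted)) {
    prows <- match(promoted, store$node_id)
    o <- order(store$node_start[prows], -store$node_stop[prows],
               store$node_label[prows], store$node_id[prows], method = "radix")
    for (pid in promoted[o]) .place_node(store, pid, s_x)
  }
  store$idx <- NULL
  invisible(removed)
}

#' Update the coordinates of a stored interval
#'
#' Implemented as removal followed by reinsertion with the new start and stop
#' positions; the label is preserved and a new node id is assigned. Invalid
#' new coordinates leave the store unchanged.
#'
#' @param store An `nclist` store (modified in place).
#' @param id Node id to update.
#' @param new_start,new_stop New half-open coordinates (`new_start <
#'   new_stop`).
#' @return The new node id, invisibly.
#' @export
nclist_update_coordinates <- function(store, id, new_start, new_stop) {
  stopifnot(inherits(store, "nclist"))
  r <- match(id, store$node_id)
  if (is.na(r)) stop("no node with id ", id, " in store", call. = FALSE)
  iv <- check_intervals(
    data.frame(chrom = store$node_chrom[r], start = as.numeric(new_start),
               stop = as.numeric(new_stop), label = store$node_label[r],
               stringsAsFactors = FALSE),
    what = "updated interval")
  nclist_delete(store, id)
  invisible(nclist_insert(store, iv))
}
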