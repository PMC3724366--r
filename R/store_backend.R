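# On-disk form: a directory holding the three relational tables as TSV
# (nodes.tsv, edges.tsv, masterkey.tsv) plus manifest.json with a format
# version, row counts, chromosome list, parent rule, the id/sub counters and
# an md5 checksum per table. Writes are atomic: everything is written to a
# temporary sibling directory which then replaces the target, so a failed
# save or edit never leaves partial files behind. The dual-sorted sublist
# index is a performance device, not logical state; it is rebuilt on load.

.STORE_FORMAT_VERSION <- 1L

.write_table <- function(df, path) {
  cols <- lapply(df, function(x) {
    if (is.numeric(x)) format(x, scientific = FALSE, trim = TRUE) else as.character(x)
  })
  lines <- c(paste(names(df), collapse = "\t"),
             if (nrow(df)) do.call(paste, c(cols, sep = "\t")))
  writeLines(lines, path)
}

.read_table <- function(path, col_classes) {
  if (!file.exists(path)) stop("corrupt store: missing table file ", basename(path),
                               call. = FALSE)
  utils::read.delim(path, colClasses = col_classes, stringsAsFactors = FALSE,
                    quote = "", comment.char = "")
}

#' Persist an NCList store to disk
#'
#' Writes the node, edge and masterkey tables (deterministically ordered by
#' id) plus a manifest with checksums to `path`, a directory that is created
#' or atomically replaced.
#'
#' @param store A valid `nclist` store.
#' @param path Target directory.
#' @return `path`, invisibly.
#' @seealso [nclist_load()], [nclist_apply_edit()]
#' @export
nclist_save <- function(store, path) {
  stopifnot(inherits(store, "nclist"))
  validate_nclist(store)
  tmp <- paste0(path, ".tmp", Sys.getpid())
  if (dir.exists(tmp)) unlink(tmp, recursive = TRUE)
  ok <- dir.create(tmp, recursive = TRUE, showWarnings = FALSE)
  if (!ok) stop("cannot create store directory at ", path, call. = FALSE)
  on.exit(if (dir.exists(tmp)) unlink(tmp, recursive = TRUE))

  .write_table(node_table(store), file.path(tmp, "nodes.tsv"))
  .write_table(edge_table(store), file.path(tmp, "edges.tsv"))
  .write_table(masterkey_table(store), file.path(tmp, "masterkey.tsv"))
  sums <- tools::md5sum(file.path(tmp, c("nodes.tsv", "edges.tsv", "masterkey.tsv")))
  manifest <- list(
    format_version = .STORE_FORMAT_VERSION,
    n_intervals = length(store$node_id),
    n_edges = nrow(edge_table(store)),
    chromosomes = sort(unique(store$node_chrom)),
    parent_rule = store$parent_rule,
    next_id = store$next_id,
    next_sub = store$next_sub,
    checksums = list(nodes = unname(sums[1]), edges = unname(sums[2]),
                     masterkey = unname(sums[3]))
  )
  jsonlite::write_json(manifest, file.path(tmp, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (dir.exists(path) || file.exists(path)) unlink(path, recursive = TRUE)
  if (!file.rename(tmp, path)) {
    stop("cannot write store to ", path, call. = FALSE)
  }
  invisible(path)
}

#' Load a persisted NCList store
#'
#' Verifies the manifest (format version, per-table md5 checksums, row
#' counts), rebuilds the in-memory store and runs the full structural
#' validator before returning.
#'
#' @param path Directory written by [nclist_save()].
#' @return An `nclist` store.
#' @export
nclist_load <- function(path) {
  mf <- file.path(path, "manifest.json")
  if (!dir.exists(path) || !file.exists(mf)) {
    stop("no store found at ", path, " (missing manifest)", call. = FALSE)
  }
  manifest <- jsonlite::read_json(mf, simplifyVector = TRUE)
  if (!identical(as.integer(manifest$format_version), .STORE_FORMAT_VERSION)) {
    stop("store format version mismatch at ", path, ": found ",
         manifest$format_version, ", expected ", .STORE_FORMAT_VERSION,
         call. = FALSE)
  }
  files <- file.path(path, c("nodes.tsv", "edges.tsv", "masterkey.tsv"))
  missing <- !file.exists(files)
  if (any(missing)) {
    stop("corrupt store: missing table file ", basename(files[missing][1]),
         call. = FALSE)
  }
  sums <- tools::md5sum(files)
  want <- c(manifest$checksums$nodes, manifest$checksums$edges,
            manifest$checksums$masterkey)
  bad <- which(unname(sums) != want)
  if (length(bad)) {
    stop("corrupt store: checksum mismatch in ", basename(files[bad[1]]),
         call. = FALSE)
  }
  nodes <- .read_table(files[1], c("numeric", "character", "numeric",
                                   "numeric", "numeric"))
  edges <- .read_table(files[2], c("numeric", "numeric"))
  mk <- .read_table(files[3], c("numeric", "character"))
  if (nrow(nodes) != manifest$n_intervals) {
    stop("corrupt store: node count (", nrow(nodes),
         ") disagrees with manifest (", manifest$n_intervals, ")", call. = FALSE)
  }
  if (nrow(edges) != manifest$n_edges) {
    stop("corrupt store: edge count disagrees with manifest", call. = FALSE)
  }
  if (nrow(mk) != nrow(nodes) || !setequal(mk$id, nodes$id)) {
    stop("corrupt store: masterkey does not cover the node ids", call. = FALSE)
  }
  store <- new_store(manifest$parent_rule)
  store$node_id <- nodes$id
  store$node_chrom <- nodes$chrom
  store$node_start <- nodes$start
  store$node_stop <- nodes$stop
  store$node_sub <- nodes$sub
  store$node_label <- mk$label[match(nodes$id, mk$id)]
  store$next_id <- as.numeric(manifest$next_id)
  store$next_sub <- as.numeric(manifest$next_sub)
  if (nrow(edges)) {
    for (i in seq_len(nrow(edges))) .add_edge(store, edges$parent_id[i],
                                              edges$child_sub[i])
  }
  validate_nclist(store)
  store
}

#' Apply a single edit to a persisted store
#'
#' Loads the store, applies one insert, delete or coordinate update through
#' the in-place update procedures, and writes the result back atomically. A
#' failed edit (invalid interval, unknown id) leaves the on-disk files
#' byte-identical to before.
#'
#' @param path Store directory.
#' @param action One of `"insert"`, `"delete"`, `"update"`.
#' @param interval For `"insert"`: the interval to add.
#' @param id For `"delete"`/`"update"`: the target node id.
#' @param new_start,new_stop For `"update"`: the new coordinates.
#' @return An edit receipt: a list with the action, the affected node id(s)
#'   and sublist value(s).
#' @export
nclist_apply_edit <- function(path, action = c("insert", "delete", "update"),
                              interval = NULL, id = NULL,
                              new_start = NULL, new_stop = NULL) {
  action <- match.arg(action)
  store <- nclist_load(path)
  receipt <- switch(action,
    insert = {
      nid <- nclist_insert(store, interval)
      r <- match(nid, store$node_id)
      list(action = "insert", node_ids = nid, subs = store$node_sub[r])
    },
    delete = {
      if (is.null(id)) stop("delete requires an id", call. = FALSE)
      r <- match(id, store$node_id)
      if (is.na(r)) stop("no node with id ", id, " in store", call. = FALSE)
      s <- store$node_sub[r]
      nclist_delete(store, id)
      list(action = "delete", node_ids = id, subs = s)
    },
    update = {
      if (is.null(id)) stop("update requires an id", call. = FALSE)
      nid <- nclist_update_coordinates(store, id, new_start, new_stop)
      r <- match(nid, store$node_id)
      list(action = "update", node_ids = c(id, nid), subs = store$node_sub[r])
    }
  )
  nclist_save(store, path)
  receipt
}
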