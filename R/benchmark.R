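# Comparator strategies for the scaling benchmark. All three answer the same
# point-annotation workload and must return identical hit sets; they differ in
# how many node records they must examine:
#   * nclist      — the indexed recursive search of this package;
#   * naive-scan  — a full table scan of every interval per query;
#   * start-sorted — intervals sorted by start per chromosome; every interval
#     with start <= pos must be examined, because nesting destroys any
#     ordering guarantee on the stops (the failure mode that motivates the
#     containment structure): there is no sound early stop.
# Operation counts, not wall time, are the primary metric: timings are
# hardware-bound, examined-node counts are not.

.bench_nclist <- function(store, positions) {
  ex <- 0
  hits <- vector("list", nrow(positions))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(positions))) {
    raw <- .nc_query_raw(store, positions$chrom[i], positions$pos[i],
                         positions$pos[i] + 1)
    ex <- ex + raw$nodes_examined
    hits[[i]] <- sort(raw$id)
  }
  list(wall_s = proc.time()[["elapsed"]] - t0, nodes_examined = ex, hits = hits)
}

.bench_naive <- function(store, positions) {
  n <- length(store$node_id)
  ex <- 0
  hits <- vector("list", nrow(positions))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(positions))) {
    p <- positions$pos[i]
    w <- which(store$node_chrom == positions$chrom[i] &
                 store$node_start <= p & store$node_stop > p)
    ex <- ex + n
    hits[[i]] <- sort(store$node_id[w])
  }
  list(wall_s = proc.time()[["elapsed"]] - t0, nodes_examined = ex, hits = hits)
}

.bench_start_sorted <- function(store, positions) {
  # per-chromosome start-sorted tables
  tabs <- list()
  for (ch in unique(store$node_chrom)) {
    rows <- which(store$node_chrom == ch)
    o <- order(store$node_start[rows], method = "radix")
    rows <- rows[o]
    tabs[[ch]] <- list(start = store$node_start[rows],
                       stop = store$node_stop[rows], id = store$node_id[rows])
  }
  ex <- 0
  hits <- vector("list", nrow(positions))
  t0 <- proc.time()[["elapsed"]]
  for (i in seq_len(nrow(positions))) {
    tb <- tabs[[positions$chrom[i]]]
    p <- positions$pos[i]
    if (is.null(tb)) { hits[[i]] <- numeric(0); next }
    k <- findInterval(p, tb$start)      # all intervals with start <= pos
    ex <- ex + k
    if (k == 0L) { hits[[i]] <- numeric(0); next }
    w <- which(tb$stop[seq_len(k)] > p)
    hits[[i]] <- sort(tb$id[w])
  }
  list(wall_s = proc.time()[["elapsed"]] - t0, nodes_examined = ex, hits = hits)
}

#' Benchmark annotation strategies on one interval database
#'
#' For each requested position-set size, annotates uniformly drawn positions
#' with every strategy, asserts that all strategies return identical hit sets
#' for every query (correctness gate), and reports wall time, total examined
#' node records and total hits.
#'
#' @param intervals Interval data frame or path to a BED file.
#' @param position_sizes Integer vector of position-set sizes.
#' @param strategies Subset of `c("nclist", "naive-scan", "start-sorted")`.
#' @param genome_length,n_chrom Genome over which positions are drawn (must
#'   match the database's coordinate space to be meaningful).
#' @param parent_rule Parent rule for the index build.
#' @param seed Optional seed for position generation.
#' @return A data frame with columns `strategy`, `db_size`, `n_queries`,
#'   `wall_s`, `nodes_examined`, `hits`.
#' @export
run_benchmark <- function(intervals, position_sizes = 1000,
                          strategies = c("nclist", "naive-scan", "start-sorted"),
                          genome_length = 1e8, n_chrom = 10,
                          parent_rule = "first", seed = NULL) {
  known <- c("nclist", "naive-scan", "start-sorted")
  bad <- setdiff(strategies, known)
  if (length(bad)) stop("unknown strategy: ", paste(bad, collapse = ", "),
                        call. = FALSE)
  if (is.character(intervals) && length(intervals) == 1L) {
    intervals <- read_bed(intervals)
  }
  store <- nclist_build(intervals[c("chrom", "start", "stop", "label")],
                        parent_rule = parent_rule)
  .refresh_index(store)
  runners <- list(`nclist` = .bench_nclist, `naive-scan` = .bench_naive,
                  `start-sorted` = .bench_start_sorted)
  out <- list()
  for (si in seq_along(position_sizes)) {
    np <- position_sizes[si]
    pos_seed <- if (is.null(seed)) NULL else seed + si
    if (np == 0) {
      next  # empty position set contributes no rows
    }
    positions <- generate_positions(np, genome_length, n_chrom, seed = pos_seed)
    res <- lapply(strategies, function(s) runners[[s]](store, positions))
    names(res) <- strategies
    if (length(strategies) > 1L) {
      ref <- res[[1]]$hits
      for (s in strategies[-1]) {
        same <- mapply(identical, ref, res[[s]]$hits)
        if (!all(same)) {
          stop("strategy disagreement: ", strategies[1], " vs ", s,
               " on query ", which(!same)[1], call. = FALSE)
        }
      }
    }
    for (s in strategies) {
      out[[length(out) + 1L]] <- data.frame(
        strategy = s, db_size = length(store$node_id), n_queries = np,
        wall_s = res[[s]]$wall_s, nodes_examined = res[[s]]$nodes_examined,
        hits = sum(lengths(res[[s]]$hits)), stringsAsFactors = FALSE)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(strategy = character(0), db_size = numeric(0),
                      n_queries = numeric(0), wall_s = numeric(0),
                      nodes_examined = numeric(0), hits = numeric(0)))
  }
  do.call(rbind, out)
}

#' Scaling experiment over database sizes
#'
#' Generates synthetic databases of the requested total sizes (base-interval
#' counts are scaled by the expected nesting multiplier so realized totals
#' land near the targets), runs a fixed point-query workload against each
#' with all strategies, and additionally checks the per-query examined-node
#' bound `nodes_examined <= hits + depth * (ceil(log2(max sublist length)) +
#' 2)` for the indexed strategy.
#'
#' @param db_sizes Target database sizes (total interval counts).
#' @param n_queries Number of point queries per database.
#' @param config A [synth_config()] used as a template (its
#'   `n_base_intervals` is overridden per size).
#' @param seed Integer seed driving both database and position generation.
#' @return A list with `results` (the [run_benchmark()] table stacked over
#'   sizes), `bound_violations` (count of queries violating the per-query
#'   bound) and `bound_checked` (number of queries checked).
#' @export
benchmark_scaling <- function(db_sizes = c(1e3, 1e4, 1e5), n_queries = 1e3,
                              config = synth_config(), seed = 1) {
  # expected intervals per base interval: sum over depths of (2 * child_prob)^d
  mult <- sum((2 * config$child_prob)^(0:(config$max_depth - 1)))
  results <- list()
  violations <- 0L
  checked <- 0L
  for (di in seq_along(db_sizes)) {
    cfg <- config
    cfg$n_base_intervals <- max(1, round(db_sizes[di] / mult))
    cfg$seed <- seed + di * 1000L
    iv <- generate_intervals(cfg)
    results[[di]] <- run_benchmark(iv, position_sizes = n_queries,
                                   genome_length = cfg$genome_length,
                                   n_chrom = cfg$n_chrom,
                                   seed = seed + di)
    # per-query bound for the indexed strategy
    store <- nclist_build(iv[c("chrom", "start", "stop", "label")])
    .refresh_index(store)
    depth <- nclist_depth(store)
    max_len <- max(table(paste(store$node_chrom, store$node_sub)))
    budget_fixed <- depth * (ceiling(log2(max_len)) + 2)
    positions <- generate_positions(n_queries, cfg$genome_length, cfg$n_chrom,
                                    seed = seed + di)
    for (i in seq_len(nrow(positions))) {
      raw <- .nc_query_raw(store, positions$chrom[i], positions$pos[i],
                           positions$pos[i] + 1)
      checked <- checked + 1L
      if (raw$nodes_examined > length(raw$id) + budget_fixed) {
        violations <- violations + 1L
      }
    }
  }
  list(results = do.call(rbind, results), bound_violations = violations,
       bound_checked = checked)
}

#' Write a benchmark table as TSV
#'
#' @param bench Output of [run_benchmark()] or the `results` element of
#'   [benchmark_scaling()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_benchmark <- function(bench, path) {
  utils::write.table(bench, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
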