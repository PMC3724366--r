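# Shared fixtures and oracles for the test suite. Everything is generated in
# code; no stored fixtures.

# Interval sets from four structural regimes, all via the synthetic generator.
regime_intervals <- function(regime = c("disjoint", "nested", "partial", "duplicate"),
                             n_base = 40, seed = 1) {
  regime <- match.arg(regime)
  cfg <- switch(regime,
    disjoint = synth_config(n_base_intervals = n_base, genome_length = 1e6,
                            n_chrom = 2, mean_length = 200, child_prob = 0,
                            partial_overlap = 0, seed = seed),
    nested = synth_config(n_base_intervals = n_base, genome_length = 2e4,
                          n_chrom = 1, mean_length = 800, child_prob = 0.8,
                          max_depth = 4, partial_overlap = 0, seed = seed),
    partial = synth_config(n_base_intervals = n_base, genome_length = 1e4,
                           n_chrom = 1, mean_length = 500, child_prob = 0.5,
                           partial_overlap = 0.6, seed = seed),
    duplicate = synth_config(n_base_intervals = n_base, genome_length = 1e4,
                             n_chrom = 1, mean_length = 400, child_prob = 0.5,
                             partial_overlap = 0.3, seed = seed)
  )
  iv <- generate_intervals(cfg)[c("chrom", "start", "stop", "label")]
  if (regime == "duplicate") {
    k <- max(1, nrow(iv) %/% 4)
    dup <- iv[seq_len(k), , drop = FALSE]
    dup$label <- paste0(dup$label, "_dup")
    iv <- rbind(iv, dup)
  }
  iv
}

# Canonical signature of a hit set: intervals compared by coordinates + label
# (node ids differ between independently built stores).
hit_sig <- function(df) sort(paste(df$start, df$stop, df$label))

# Query a store and the brute-force oracle; TRUE iff identical hit sets.
query_matches_oracle <- function(store, intervals, chrom, q_start, q_stop) {
  h <- nclist_query(store, chrom, q_start, q_stop)
  bf <- brute_force_overlap(intervals, chrom, q_start, q_stop)
  identical(hit_sig(h), hit_sig(bf))
}

# Exhaustive probe grid: every distinct boundary coordinate +/- 1 as a point
# query (hit sets only change at interval boundaries).
probe_grid <- function(intervals, chrom) {
  b <- c(intervals$start[intervals$chrom == chrom],
         intervals$stop[intervals$chrom == chrom])
  p <- sort(unique(c(b - 1, b, b + 1)))
  p[p >= 0]
}

# TRUE iff the store answers every grid probe identically to a brute-force
# scan of `intervals` (the rebuild / ground-truth oracle).
store_equiv <- function(store, intervals) {
  if (nrow(intervals) == 0L) return(length(store$node_id) == 0L)
  for (ch in unique(intervals$chrom)) {
    for (p in probe_grid(intervals, ch)) {
      h <- nclist_query_point(store, ch, p)
      bf <- brute_force_overlap(intervals, ch, p, p + 1)
      if (!identical(hit_sig(h), hit_sig(bf))) return(FALSE)
    }
  }
  TRUE
}

# Run one random interleaved insert/delete script against an empty store,
# validating after every edit. Returns list(store, live, violations).
run_edit_script <- function(n_edits, seed, p_delete = 0.4) {
  set.seed(seed)
  pool <- regime_intervals("partial", n_base = 40, seed = seed)
  st <- nclist_build(pool[0, ])
  live <- pool[0, ]
  violations <- character(0)
  for (e in seq_len(n_edits)) {
    if (length(st$node_id) > 0 && stats::runif(1) < p_delete) {
      vid <- st$node_id[sample.int(length(st$node_id), 1)]
      rem <- nclist_delete(st, vid)
      m <- which(live$chrom == rem$chrom & live$start == rem$start &
                   live$stop == rem$stop & live$label == rem$label)[1]
      live <- live[-m, , drop = FALSE]
    } else {
      r <- pool[sample.int(nrow(pool), 1), , drop = FALSE]
      if (stats::runif(1) < 0.3) {
        w <- r$stop - r$start
        r$start <- max(0, r$start + sample(-5:5, 1))
        r$stop <- r$start + max(1, w + sample(-5:5, 1))
      }
      r$label <- paste0(r$label, "_e", e)
      nclist_insert(st, r)
      live <- rbind(live, r)
    }
    v <- nclistdb:::store_violations(st)
    if (length(v)) {
      violations <- c(violations, paste0("edit ", e, ": ", v[1]))
      break
    }
  }
  list(store = st, live = live, violations = violations)
}

# Football-roster worked example: careers as half-open year ranges
# [first_year, last_year + 1). The non-nested players A-E sort identically by
# start and stop; the nested players L-P do not.
roster_intervals <- function() {
  genomic_intervals(
    chrom = rep("team", 10),
    start = c(1998, 2001, 2004, 2006, 2009, 1995, 2000, 2004, 2005, 2010),
    stop  = c(2004, 2006, 2008, 2011, 2013, 2013, 2010, 2008, 2007, 2012),
    label = c("A", "B", "C", "D", "E", "L", "M", "N", "O", "P")
  )
}
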