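test_that("the nested football roster answers 'who played in 2008' correctly", {
  st <- nclist_build(roster_intervals())
  hits <- nclist_query_point(st, "team", 2008)
  # player C's 2004-2007 career ends before 2008, so C is not a hit; neither
  # is the nested player N with the same years. M joined before N but stayed
  # past 2008 and must not be skipped.
  expect_false("C" %in% hits$label)
  expect_false("N" %in% hits$label)
  expect_setequal(hits$label, c("D", "L", "M"))
})

test_that("query boundaries follow the half-open convention exactly", {
  st <- nclist_build(genomic_intervals("chr1", 10, 20, "iv"))
  yes <- function(a, b) expect_equal(nclist_query(st, "chr1", a, b)$label, "iv")
  no <- function(a, b) expect_equal(nrow(nclist_query(st, "chr1", a, b)), 0L)
  # range queries around both boundaries
  no(20, 21)   # abuts the stop
  no(9, 10)    # abuts the start
  yes(19, 20)  # last covered base
  yes(10, 11)  # first covered base
  no(0, 10)    # ends at the start
  no(20, 30)   # begins at the stop
  yes(5, 25)   # spans the interval
  yes(12, 15)  # inside the interval
  # point queries: a point equals a width-1 range
  expect_equal(nrow(nclist_query_point(st, "chr1", 20)), 0L)  # pos == stop
  expect_equal(nclist_query_point(st, "chr1", 10)$label, "iv")
  expect_equal(nrow(nclist_query_point(st, "chr1", 9)), 0L)
  expect_equal(nclist_query_point(st, "chr1", 19)$label, "iv")
  # abutting intervals share a coordinate but never a position
  st2 <- nclist_build(genomic_intervals("chr1", c(10, 20), c(20, 30), c("l", "r")))
  expect_equal(nclist_query_point(st2, "chr1", 20)$label, "r")
})

test_that("queries validate inputs and tolerate unknown chromosomes", {
  st <- nclist_build(genomic_intervals("chr1", 0, 10, "a"))
  expect_error(nclist_query(st, "chr1", 5, 5), "q_start < q_stop")
  expect_error(nclist_query(st, "chr1", 7, 2), "q_start < q_stop")
  expect_equal(nrow(nclist_query(st, "chrUn", 0, 100)), 0L)
  empty <- nclist_build(genomic_intervals("chr1", 0, 10, "a")[0, ])
  expect_equal(nrow(nclist_query(empty, "chr1", 0, 100)), 0L)
})

test_that("point queries inside a nested chain return every enclosing level", {
  st <- nclist_build(genomic_intervals("chr1", c(0, 2, 4), c(20, 10, 6),
                                       c("x", "y", "z")))
  h <- nclist_query_point(st, "chr1", 5)
  expect_equal(h$label, c("x", "y", "z"))  # start asc, stop desc ordering
  expect_equal(nrow(nclist_query_point(st, "chr1", 30)), 0L)
})

test_that("indexed queries equal the brute-force oracle across regimes", {
  set.seed(77)
  for (regime in c("disjoint", "nested", "partial", "duplicate")) {
    for (seed in 1:8) {
      iv <- regime_intervals(regime, n_base = 40, seed = seed)
      st <- nclist_build(iv)
      chroms <- unique(iv$chrom)
      span <- max(iv$stop)
      for (q in 1:5) {
        ch <- chroms[sample.int(length(chroms), 1)]
        a <- floor(runif(1, 0, span))
        b <- a + floor(runif(1, 1, span / 4))
        expect_true(query_matches_oracle(st, iv, ch, a, b),
                    info = paste(regime, seed, ch, a, b))
      }
    }
  }
})

test_that("independent interval-tree library agrees with both query routes", {
  iv <- regime_intervals("partial", n_base = 60, seed = 5)
  st <- nclist_build(iv)
  ir <- IRanges::IRanges(start = iv$start + 1, end = iv$stop)  # 1-based closed
  set.seed(42)
  for (q in 1:50) {
    a <- floor(runif(1, 0, 9000)); b <- a + floor(runif(1, 1, 1500))
    h <- nclist_query(st, "chr1", a, b)
    bf <- brute_force_overlap(iv, "chr1", a, b)
    ov <- IRanges::findOverlaps(IRanges::IRanges(a + 1, b), ir)
    idx <- sort(S4Vectors::subjectHits(ov))
    expect_identical(hit_sig(h), hit_sig(iv[idx, , drop = FALSE]))
    expect_identical(hit_sig(h), hit_sig(bf))
  }
})

test_that("operation counters bound the work and never undercount hits", {
  iv <- regime_intervals("nested", n_base = 60, seed = 9)
  st <- nclist_build(iv)
  set.seed(1)
  for (q in 1:40) {
    a <- floor(runif(1, 0, 19000)); b <- a + floor(runif(1, 1, 3000))
    h <- nclist_query(st, "chr1", a, b)
    expect_gte(attr(h, "nodes_examined"), nrow(h))
    expect_gte(attr(h, "sublists_entered"), if (nrow(h)) 1L else 0L)
  }
})

test_that("enlarging a query range never loses hits", {
  iv <- regime_intervals("partial", n_base = 40, seed = 13)
  st <- nclist_build(iv)
  set.seed(2)
  for (q in 1:30) {
    a <- floor(runif(1, 0, 8000)); b <- a + floor(runif(1, 1, 800))
    inner <- nclist_query(st, "chr1", a, b)$id
    outer <- nclist_query(st, "chr1", max(0, a - 50), b + 50)$id
    expect_true(all(inner %in% outer))
  }
})

test_that("annotation emits one row per overlap and a null row otherwise", {
  st <- nclist_build(genomic_intervals("chr1", c(0, 5), c(10, 15), c("a", "b")))
  ann <- annotate_positions(st, genomic_positions(c("chr1", "chr1", "chr2"),
                                                  c(7, 100, 3)))
  expect_equal(nrow(ann), 4L)  # 2 hits + 2 null rows
  expect_equal(ann$label, c("a", "b", ".", "."))
  expect_true(all(is.na(ann$feature_id[ann$label == "."])))
  expect_equal(ann$pos, c(7, 7, 100, 3))  # input order preserved

  empty <- annotate_positions(st, genomic_positions(character(0), numeric(0)))
  expect_equal(nrow(empty), 0L)
})

test_that("batch annotation equals the brute-force join on random inputs", {
  iv <- regime_intervals("partial", n_base = 80, seed = 21)
  st <- nclist_build(iv)
  pos <- generate_positions(400, genome_length = 1e4, n_chrom = 1, seed = 22)
  ann <- annotate_positions(st, pos)
  n_hit_rows <- 0
  for (i in seq_len(nrow(pos))) {
    bf <- brute_force_overlap(iv, pos$chrom[i], pos$pos[i], pos$pos[i] + 1)
    rows <- ann[ann$pos == pos$pos[i] & ann$chrom == pos$chrom[i] &
                  ann$label != ".", , drop = FALSE]
    got <- sort(paste(rows$feature_start, rows$feature_stop, rows$label))
    expect_identical(unique(got), unique(hit_sig(bf)))
    n_hit_rows <- n_hit_rows + nrow(bf)
  }
  expect_equal(sum(ann$label != "."), n_hit_rows)
})

test_that("annotation TSV uses the dot marker for missing features", {
  st <- nclist_build(genomic_intervals("chr1", 0, 10, "a"))
  ann <- annotate_positions(st, genomic_positions("chr1", c(5, 50)))
  f <- withr::local_tempfile()
  write_annotations(ann, f)
  lines <- readLines(f)
  expect_equal(lines[1], "chrom\tpos\tlabel\tfeature_start\tfeature_stop\tfeature_id")
  expect_equal(lines[3], "chr1\t50\t.\t.\t.\t.")
})
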