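test_that("insertion handles all five structural conditions", {
  # (A) root level, contains nothing: plain append to sublist 0
  st <- nclist_build(genomic_intervals("chr1", 0, 10, "a")[0, ])
  nclist_insert(st, genomic_intervals("chr1", 0, 10, "a"))
  expect_equal(node_table(st)$sub, 0)
  expect_equal(nrow(edge_table(st)), 0L)

  # (B) root level, contains a root interval: that interval moves to a fresh
  # sublist with an edge from the new node
  st <- nclist_build(genomic_intervals("chr1", 0, 10, "a"))
  nid <- nclist_insert(st, genomic_intervals("chr1", 0, 50, "b"))
  nt <- node_table(st)
  expect_equal(nt$sub[nt$id == nid], 0)
  moved_sub <- nt$sub[nt$id == 1]
  expect_gt(moved_sub, 0)
  expect_equal(edge_table(st), data.frame(parent_id = nid, child_sub = moved_sub))
  expect_true(store_equiv(st, genomic_intervals("chr1", c(0, 0), c(10, 50), c("a", "b"))))

  # (C) contained, and contains members of the target sublist: takes the sub
  # value of its child; the child moves to a fresh sublist
  st <- nclist_build(genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b")))
  nid <- nclist_insert(st, genomic_intervals("chr1", 5, 50, "c"))
  nt <- node_table(st)
  expect_equal(nt$sub[nt$id == nid], 1)              # the sub b had
  expect_equal(nt$sub[nt$id == 2], 2)                # b moved to fresh sub
  et <- edge_table(st)
  expect_equal(et$child_sub[et$parent_id == nid], 2)
  expect_true(store_equiv(st, genomic_intervals(
    "chr1", c(0, 10, 5), c(100, 20, 50), c("a", "b", "c"))))

  # (D) contained, childless, parent already has a sublist: joins it
  st <- nclist_build(genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b")))
  nid <- nclist_insert(st, genomic_intervals("chr1", 40, 60, "d"))
  nt <- node_table(st)
  expect_equal(nt$sub[nt$id == nid], nt$sub[nt$id == 2])
  expect_equal(nrow(edge_table(st)), 1L)

  # (E) contained, childless, parent has no sublist: fresh sub + parent edge
  st <- nclist_build(genomic_intervals("chr1", 0, 100, "a"))
  nid <- nclist_insert(st, genomic_intervals("chr1", 10, 20, "e"))
  nt <- node_table(st)
  s <- nt$sub[nt$id == nid]
  expect_gt(s, 0)
  expect_equal(edge_table(st), data.frame(parent_id = 1, child_sub = s))
})

test_that("inserting an interval containing part of a sublist moves only that part", {
  st <- nclist_build(genomic_intervals("chr1", c(0, 10, 40), c(100, 20, 60),
                                       c("a", "b", "c")))
  # b and c are siblings under a; the new node contains only b
  nid <- nclist_insert(st, genomic_intervals("chr1", 5, 30, "x"))
  nt <- node_table(st)
  expect_equal(nt$sub[nt$id == nid], nt$sub[nt$id == 3])  # x joins c's sublist
  expect_gt(nt$sub[nt$id == 2], nt$sub[nt$id == 3])       # b moved below x
  expect_silent(validate_nclist(st))
  expect_true(store_equiv(st, genomic_intervals(
    "chr1", c(0, 10, 40, 5), c(100, 20, 60, 30), c("a", "b", "c", "x"))))
})

test_that("deletion handles leaves, sole children, and promotions", {
  # delete the only node -> empty store
  st <- nclist_build(genomic_intervals("chr1", 0, 10, "a"))
  rem <- nclist_delete(st, 1)
  expect_equal(rem$label, "a")
  expect_equal(length(st$node_id), 0L)
  expect_length(nclistdb:::store_violations(st), 0)

  # root with children: children promoted to sublist 0, edge dropped
  st <- nclist_build(genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b")))
  nclist_delete(st, 1)
  expect_equal(node_table(st)$sub, 0)
  expect_equal(nrow(edge_table(st)), 0L)

  # internal node with children: children take the deleted node's sub value
  iv <- genomic_intervals("chr1", c(0, 10, 12), c(100, 20, 15), c("a", "b", "c"))
  st <- nclist_build(iv)
  nclist_delete(st, 2)  # b
  nt <- node_table(st)
  expect_equal(nt$sub[nt$id == 3], 1)  # c now holds b's old sub
  expect_equal(edge_table(st), data.frame(parent_id = 1, child_sub = 1))

  # sole member of a sublist: the parent's edge is removed
  st <- nclist_build(genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b")))
  nclist_delete(st, 2)
  expect_equal(nrow(edge_table(st)), 0L)
  expect_equal(node_table(st)$sub, 0)
})

test_that("deletion re-attaches promoted children under a containing sibling", {
  # c sits under a (first-parent rule); b partially overlaps a and strictly
  # contains c. Deleting a promotes c beside b; containment repair must move
  # c beneath b or the sublist would nest internally.
  iv <- genomic_intervals("chr1", c(0, 5, 6), c(10, 15, 9), c("a", "b", "c"))
  st <- nclist_build(iv)
  expect_equal(edge_table(st)$parent_id, 1)
  nclist_delete(st, 1)
  nt <- node_table(st)
  et <- edge_table(st)
  expect_equal(et$parent_id, 2)                       # b now parents c
  expect_equal(nt$sub[nt$id == 3], et$child_sub)
  expect_length(nclistdb:::store_violations(st), 0)
  expect_true(store_equiv(st, iv[-1, ]))
})

test_that("insert followed by delete restores query behaviour", {
  for (seed in 1:20) {
    iv <- regime_intervals("partial", n_base = 25, seed = seed)
    st <- nclist_build(iv)
    set.seed(seed)
    x <- genomic_intervals("chr1", floor(runif(1, 0, 5000)),
                           floor(runif(1, 5000, 9000)), "probe")
    nid <- nclist_insert(st, x)
    nclist_delete(st, nid)
    expect_length(nclistdb:::store_violations(st), 0)
    expect_true(store_equiv(st, iv), info = paste("seed", seed))
  }
})

test_that("coordinate update behaves as remove plus reinsert", {
  iv <- genomic_intervals("chr1", c(0, 10, 12), c(100, 20, 15), c("a", "b", "c"))
  st <- nclist_build(iv)
  # identical coordinates: store stays query-equivalent
  nid <- nclist_update_coordinates(st, 2, 10, 20)
  expect_false(nid == 2)  # new id assigned
  expect_true(store_equiv(st, iv))
  # label preserved
  expect_true("b" %in% masterkey_table(st)$label)

  # shrink a parent below its child's range: child promoted, then reinsertion
  st <- nclist_build(iv)
  nclist_update_coordinates(st, 2, 16, 18)  # b no longer contains c
  after <- genomic_intervals("chr1", c(0, 16, 12), c(100, 18, 15), c("a", "b", "c"))
  expect_length(nclistdb:::store_violations(st), 0)
  expect_true(store_equiv(st, after))

  # widen a leaf to contain its former sibling
  st <- nclist_build(genomic_intervals("chr1", c(0, 30), c(10, 40), c("a", "b")))
  nclist_update_coordinates(st, 2, 0, 50)
  et <- edge_table(st)
  expect_equal(nrow(et), 1L)  # a is now b's child
  expect_true(store_equiv(st, genomic_intervals("chr1", c(0, 0), c(10, 50),
                                                c("a", "b"))))
})

test_that("failed edits leave the store untouched", {
  iv <- genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b"))
  st <- nclist_build(iv)
  before_nodes <- node_table(st)
  before_edges <- edge_table(st)
  expect_error(nclist_insert(st, genomic_intervals("chr1", 5, 50, "x")[0, ]),
               "exactly one")
  expect_error(nclist_insert(st, data.frame(chrom = "chr1", start = 9,
                                            stop = 5, label = "bad")),
               "start >= stop")
  expect_error(nclist_delete(st, 999), "no node with id 999")
  expect_error(nclist_update_coordinates(st, 2, 30, 30), "start >= stop")
  expect_error(nclist_update_coordinates(st, 999, 0, 1), "no node")
  expect_identical(node_table(st), before_nodes)
  expect_identical(edge_table(st), before_edges)
})

test_that("sub values are never recycled across edits", {
  st <- nclist_build(genomic_intervals("chr1", c(0, 10), c(100, 20), c("a", "b")))
  subs_seen <- max(node_table(st)$sub)
  for (k in 1:10) {
    # each insert makes a fresh sublist under b; each delete empties it and
    # drops the edge, but the sub counter must keep advancing
    nid <- nclist_insert(st, genomic_intervals("chr1", 12, 14, paste0("x", k)))
    s <- node_table(st)$sub[node_table(st)$id == nid]
    expect_gt(s, subs_seen)
    subs_seen <- s
    nclist_delete(st, nid)
  }
  expect_equal(subs_seen, 11)  # 1 from build + 10 fresh, none recycled
})
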