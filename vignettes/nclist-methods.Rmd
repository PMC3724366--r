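---
title: "Nested containment lists as relational tables: model, algorithms, and design decisions"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Nested containment lists as relational tables}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(nclistdb)
```

## 1. The data model

A feature database is a set of intervals on named chromosomes. All
coordinates are **0-based, half-open** `[start, stop)`, the BED convention.
Two intervals overlap iff

```
a.start < b.stop  &&  a.stop > b.start
```

with strict inequalities, so abutting intervals do not overlap, and a point
query at position `p` is the width-one range `[p, p + 1)`: a feature whose
`stop` equals `p` is not a hit.

Interval `a` **strictly contains** `b` iff `a.start <= b.start`,
`a.stop >= b.stop`, and `(a.start, a.stop) != (b.start, b.stop)`. Intervals
with identical coordinates never nest — they are siblings. This strictness
is load-bearing: if equal intervals could nest, containment would not be
antisymmetric, the parent relation would depend on insertion order, and
duplicate features (a common reality in annotation data) would produce
chains of depth equal to their multiplicity, destroying the query bound.

The nested containment list stores this as a forest, represented by three
relational tables:

| table       | columns                           | meaning                                      |
|-------------|-----------------------------------|----------------------------------------------|
| `node`      | `id, chrom, start, stop, sub`     | one row per interval; `sub` = owning sublist |
| `edge`      | `parent_id, child_sub`            | one row per interval that has nested children |
| `masterkey` | `id, label`                       | numeric id to feature label                  |

`sub = 0` is the per-chromosome root sublist. Every other sublist id appears
in exactly one edge row, so sublist membership plus the edge table encode
the parent function completely. Sublist ids are allocated from a monotone
counter and **never recycled**, even when a delete empties a sublist;
recycling would let a stale reference silently point at an unrelated
sublist after a crash-and-reload.

The structural invariant is: **within any one sublist, restricted to one
chromosome, no interval contains another.** Consequently, sorting a sublist
by `(start asc, stop desc)` also sorts it by `stop` ascending over distinct
intervals, and binary search is valid on either endpoint.
`validate_nclist()` checks this invariant, plus edge consistency, masterkey
coverage, absence of orphan sublists, and counter sanity; it runs after
every load and before every save.

## 2. Batch construction

`nclist_build()` sorts by `(chrom, start asc, stop desc, label asc)`. The
`stop`-descending tie-break guarantees a container precedes everything it
contains, so one forward pass suffices. The pass maintains an *active set*:
indices of already-placed intervals whose `stop` exceeds the current
interval's `start`. Among active intervals, those that strictly contain the
current one are its candidate parents; the candidates that do not strictly
contain another candidate are its **minimal containers**.

When an interval has several minimal containers (possible only when
candidates partially overlap each other), a deterministic `parent_rule`
picks one: `"first"` (the default) takes the earliest minimal container in
sort order, `"last"` takes the latest, i.e. the nearest enclosing interval.
A simple stack-based construction naturally yields `"last"`; the active-set
formulation supports both rules and is verified against
`containment_forest_oracle()`, a quadratic reference implementation that
computes the same parent relation by exhaustive pairwise containment tests.

## 3. Queries

A range query `[q_start, q_stop)` proceeds sublist by sublist, starting from
the chromosome root. In each sublist (sorted on both endpoints), a binary
search finds the first member with `stop > q_start`; a forward scan then
collects members while `start < q_stop`. Every hit that owns a sublist
enqueues it, because anything overlapping the query inside a non-hit is
impossible — a child is contained in its parent, so a non-overlapping
parent screens its entire subtree.

Queries are instrumented: `nodes_examined` counts binary-search probes plus
scanned rows (including the single overshoot row that terminates each
scan), and `sublists_entered` counts descents. Per query this is bounded by

```
nodes_examined  <=  hits + depth * (ceil(log2(max sublist length)) + 2)
```

which the benchmark harness checks for every individual query it runs.
Hits are returned ordered by `(start asc, stop desc, id asc)`.

`annotate_positions()` joins a position table against the store, one output
row per (position, hit) pair, with a placeholder row (label `"."`) for
positions with no hits, preserving input order — the relational analogue of
an outer join.

## 4. Incremental maintenance

**Insert** descends from the root: if the new interval has containers in the
current sublist, recurse into the rule-selected minimal container's child
sublist (creating the sublist and edge if the container had no children).
Otherwise the interval settles in the current sublist, and any members it
now strictly contains are captured: moved into its (possibly fresh) child
sublist, recursively re-placed so the invariant holds among them.

**Delete** promotes the deleted node's children into the sublist the node
occupied, removes the node and its edge, and removes the parent's edge if
the deleted node was the sole member of its sublist. Promotion can put a
child next to a sibling that contains it, so each promoted child is
re-placed with the same descent procedure (*containment repair*).

**Coordinate update** is delete + reinsert under a new id with the label
preserved, validated before any mutation so a rejected update changes
nothing.

A deliberate divergence: batch construction selects a parent among minimal
containers computed over the *whole* input, while an insert descends level
by level and applies the rule *locally* at each sublist. With partial
overlaps among containers the two can choose different (both valid)
parents, so an incrementally grown store is not guaranteed to be
node-table-identical to a fresh rebuild. It is guaranteed — and extensively
tested — to be **query-equivalent**: identical hit sets for every query,
with all invariants intact after every edit. Exact structural agreement is
asserted where it is well-defined (insert/delete reversibility, the
oracle-checked batch path).

## 5. Persistence

`nclist_save()` writes the three tables as TSV plus a `manifest.json`
carrying the format version, row counts, the `parent_rule`, both allocation
counters, and an MD5 checksum per table. Writes go to a temporary sibling
directory which then atomically replaces the target, so a crash mid-save
leaves the previous store intact. `nclist_load()` verifies the version,
checksums, and counts, then runs the full structural validator before
returning. The in-memory query index is rebuilt lazily from the node table,
so it is never serialized and can never be stale on disk.

`nclist_apply_edit()` is the transactional edit path: load, validate, edit,
validate, save. A failing edit raises an error before anything is written,
leaving every file byte-identical — checked in the tests with checksums.

The store is a directory of text tables rather than an embedded SQL
database because the deployment target guarantees only base R plus
`jsonlite`; the representation is nevertheless exactly the three relations
above, and the edge/masterkey/node vocabulary matches what one would create
as SQL tables.

## 6. Synthetic data generator

`generate_intervals()` produces annotation-like interval sets from a
`synth_config()`. Defaults were fixed a priori to resemble exon-scale
genomic features and are study conditions, not tuning knobs:

* 10 chromosomes of 10 Mb (positions stay far below 2^31),
* lognormal feature lengths, mean 150 bp, `sdlog` 0.8,
* each interval spawns `Binomial(2, 0.3)` strictly-contained children, to
  `max_depth = 4`, with child length a uniform fraction in `[0.2, 0.6]` of
  the parent,
* 15% of intervals are shifted onto a neighbour's midpoint to create
  genuine partial overlaps, the regime where containment-based structures
  must be correct but get no help.

`generate_positions()` draws query positions uniformly. Everything is
reproducible from a single seed.

## 7. Benchmarks

`run_benchmark()` compares three strategies on the *same* positions —
`nclist`, `naive-scan` (examines every row per query), and `start-sorted`
(per-chromosome binary search on `start`, then a backward scan over
everything with `start <= pos`, which must examine every earlier-starting
row because any of them could still cover the position). Hit sets are
asserted identical across strategies before any number is reported.
**Operation counts are the primary metric**; wall-clock seconds are
reported for orientation but never asserted, since they are
machine-dependent. `benchmark_scaling()` runs the decade experiment
(e.g. 10³/10⁴/10⁵ intervals) and additionally checks the per-query
examined-rows bound of section 3 for every query.

Observed shape (1,000 point queries per size, defaults above): naive
examined rows grow ~10× per decade of database size; NCList examined rows
grow ~1.3–1.5× per decade, i.e. roughly logarithmically, at about 7–13 rows
per query.

## 8. Problem sizes and limitations

The test and acceptance workloads use interval sets from tens to 10⁵ rows,
nesting depth ≤ 4, edit scripts of 50–300 interleaved inserts and deletes,
and thousands of instrumented queries; all oracle comparisons (brute force,
containment forest, batch rebuild) run at those sizes.

Known limitations:

* Inserts and deletes are O(depth × sublist length) per edit — fine for
  interactive maintenance, not for bulk loads (use `nclist_build`).
* The on-disk format rewrites whole tables per transactional edit; it
  favours integrity and auditability over write throughput.
* No strand or per-feature metadata beyond the label; extra BED columns are
  ignored on input.
* Single-writer persistence; there is no file locking.
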