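---
title: "Interval joins in rangekit: model, algorithms, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Interval joins in rangekit: model, algorithms, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rangekit)
library(tibble)
```

# The model

`rangekit` treats a set of genomic features as a table: one row per
feature, designated columns `chrom` (contig name), `start` and `end`
(base-pair positions), and any number of payload columns that operations
carry through untouched. Row order is meaningful — row *i* is feature *i*,
and that identity is stable under reading, sorting of outputs, and
batching. Contig names are opaque strings compared by exact equality;
`"chr1"` and `"1"` are different contigs, and no aliasing or prefix
normalization is ever applied, because silent renaming corrupts joins. A
future normalizer should be an explicit, visible step.

Two coordinate conventions coexist in the standard file formats, and both
are first-class here:

* **0-based half-open** `[start, end)` — BED. Length is `end − start`, and
  `start == end` is a legal zero-length (point-like) span.
* **1-based closed** `start..end` — GFF3, VCF. Both endpoints included,
  `start ≥ 1`, no zero-length representation.

All interval arithmetic runs internally in half-open coordinates, where
intersection, length, and gap computations need no ±1 corrections and
zero-length spans are representable. Frames tagged 1-based convert on
entry (`start − 1`) and convert back on output, so callers always see
their own system. The round trip is exact. The one asymmetry: a
zero-length half-open interval cannot be expressed 1-based, so converting
one is an error rather than a silent drop. We likewise decided that the
1-based representation never admits zero-length features (the formats that
use it have none), while the internal half-open space does.

Zero-length spans behave as points: `(p, p)` overlaps `[s, e)` iff
`s ≤ p < e`, on whichever side of the join it appears; two points never
overlap (they share no base). This keeps overlap consistent with half-open
intersection. Insertion sites and cut positions are the intended use.

## The four operations

For probe interval *a* and build interval *b* on the same contig:

* `iv_overlap(a, b)` — pairs with `b.start < a.end && a.start < b.end`.
  Book-ended intervals (`a.end == b.start`) do **not** overlap.
* `iv_nearest(a, b, k)` — distance
  `d(a, b) = max(0, b.start − a.end, a.start − b.end)`: the gap in bases,
  0 when overlapping *or* touching. Note the deliberate asymmetry:
  touching intervals have distance 0 yet do not overlap. The distance is
  the half-open coordinate difference, i.e. the number of bases strictly
  between the two intervals.
* `iv_count_overlaps(a, b)` — per probe row, the number of overlapping
  build rows. Duplicated build rows each count: all operations are
  multiset-faithful, and no implicit deduplication ever happens.
* `iv_coverage(a, b)` — `|a ∩ ⋃B|` in base pairs, computed against the
  merged union of the build side so stacked intervals never double-count,
  plus `coverage_fraction = covered / length(a)`, defined as 0 for a
  zero-length probe (avoiding 0/0).

Nearest ties at equal distance are broken by smaller build start, then
smaller end, then smaller row number — a total order, so results are
reproducible. With `k > 1` the operation returns distinct build *rows*,
not distinct distances, matching join-row semantics. These tie rules are
this package's contract; other tools differ, and comparisons across tools
should sort by distance only.

The build/probe assignment is fixed: the second argument `b` is always
indexed, the first argument `a` always scanned, matching the "for each
interval in A" phrasing of every operation. No automatic side-swapping by
size is performed; an optimizer that swaps sides would change memory
behavior invisibly, which matters once the probe side streams.

# The index

The search structure over the build side is an augmented interval list.
Per contig, intervals are sorted by `(start, end, input order)` and
annotated with a running maximum of end positions. An overlap query binary
searches for the last start below the query end, then scans backward; the
scan stops as soon as the running maximum falls below the query start,
because no earlier interval can then reach the query. On data without
extreme containment, a query inspects `O(log n + hits)` entries.

Long intervals that contain many others inflate the running maximum and
blunt the pruning. The classic remedy is decomposition: at build time, an
interval that covers more than 10 of the 20 intervals that follow it in
start order is promoted to the next component, repeated up to 10
components (components smaller than 64 intervals are not decomposed
further). Each component keeps its own running maximum and is scanned
independently. The thresholds are the conventional ones for this
structure; they only affect speed, never results, and the unit tests
assert the inspected-candidate bound on sparse data
(`≤ 2·(log₂ n + hits + 8)` per query).

Nearest queries expand outward from the start-insertion point with
per-frontier lower bounds (right frontier: `start − query.end`; left
frontier: `query.start − running_max_end`), pruned against the current
k-th best distance; candidates at the bound are kept so ties resolve by
the stated order. The index is immutable — repeated queries return
identical results — and lives per join; dynamic insertion and on-disk
persistence are out of scope.

The kernels (build, overlap/count scan, nearest expansion) are C++ via
Rcpp, as is usual for interval engines in R. Coordinates travel as R
doubles and are handled as 64-bit integers internally: exact up to 2⁵³,
comfortably past any genome length and past the row counts of joined
outputs, where 32-bit counters can overflow. Validation rejects negative
starts and non-integer coordinates row-wise, reporting each offending row
number and reason; missing or non-numeric coordinate *columns* are a
structural error instead.

# Streaming execution

Each operation is per-probe-row: given the build index, a probe row's
output depends on nothing else. The streaming executor exploits this
directly — `iv_stream()` materializes only the build state (index, or
merged union table for coverage), pulls probe batches from an iterator,
validates and processes each batch, and emits (and optionally appends to a
TSV/CSV sink) that batch's output before pulling the next. Peak probe-side
memory is one batch plus one output batch, and the executor's
instrumented counter (`stream_stats$max_probe_rows_retained`) proves it in
the tests. Concatenated streamed output equals the eager result row for
row, a property the suite checks for every operation at batch sizes 1, 7,
64, and 4096.

The default batch size is 65 536 rows — large enough that per-batch
overhead is negligible, small enough that a batch of typical interval rows
stays in the tens of megabytes. The executor is a pull-based iterator
protocol (`function()` returning `list(data, batch_index, is_last)` or
`NULL`); nothing in the contract forbids a parallel implementation, but
none is required, and correctness is stated as multiset equality so a
future parallel executor has room to reorder. A fully-streamed *build*
side (external-memory index) is deliberately out of scope: one side must
be resident for an index join, and which side that is, is part of the API
contract.

`iv_scan()` streams files the same way, holding at most one batch of
parsed rows: raw lines are read in bounded chunks, comment/header lines
filtered per format, and exactly `batch_size` data rows parsed per yield.
A malformed line raises an error naming the file and line number when its
batch is reached — batches before it have already been yielded, which is
the honest behavior for a streaming parser.

# File formats

The readers implement the coordinate conventions exactly: BED is tagged
half-open; GFF3 and VCF 1-based closed. Choices worth knowing:

* **VCF interval span**: `start = POS`, `end = POS + nchar(REF) − 1`. The
  REF span is what the record physically occupies; `INFO END` and symbolic
  ALT structural-variant spans are *not* interpreted, a documented
  limitation that keeps the reader free of INFO-field semantics and is the
  right behavior for SNV/INDEL annotation work. Users who need symbolic SV
  ends can compute `end` from the parsed raw `info` string themselves.
* **GFF3 attributes stay raw**: column 9 is carried as one string. The
  attribute schema is open-ended, and unpacking it is a separate concern
  from interval arithmetic; a `##FASTA` trailer halts parsing per the
  format.
* **BED extras**: `name`, `score`, `strand`, then opaque `col7`… strings.
  BED12 block semantics are not needed by interval operations.
* Gzip input is detected by magic bytes for all text formats; CRLF is
  tolerated. Output (`write_table()`) writes `NA` as empty fields and
  round-trips through a `na = ""` read.

# The synthetic generator

`iv_generate()` emulates the synthetic benchmark shape common in the
interval-library literature: `n` intervals placed uniformly over one or
more contigs, with fixed, uniform, or geometric lengths. The default
profile — one 250 Mbp contig, fixed 1 kb lengths — approximates the
standard synthetic design; the paired form scales the published
real-data shape (10⁷ vs 1.2×10⁶ intervals) down for desk work.

Randomness is a counter-based splitmix64 mix of `(seed, row, stream)`,
fixed forever by this package, rather than R's RNG: fixture generation is
bit-reproducible across platforms, sessions, and languages, and generating
row *i* needs no state from rows before it. Contig choice and start
placement use integer-only arithmetic (`mix mod range`); the geometric
length model is the one non-integer path (a float inverse-CDF on the mixed
53-bit uniform), which is deterministic on a given platform and agrees in
distribution everywhere. The generator produces what it claims and nothing
more: uniform placement has no clustering, no telomere/centromere
structure, no length/position correlation, and no real length
distribution. Passing oracle tests on generated data therefore
demonstrates algorithmic correctness, not robustness to every real-data
pathology — which is why the test oracles also run on adversarial shapes
(stacked duplicates, containment, touching endpoints, zero-length spans).

# Validation strategy and problem sizes

Every operation is checked against an independent brute-force oracle that
shares no code with the engine: nested-loop scans for overlap, counts and
nearest; per-base bitmaps for union and coverage. The acceptance suite
runs 200 seeded random instances (up to 500 intervals per side,
coordinates below 10⁵, 1–3 contigs, zero-length spans included) and
additionally asserts the definitional identities on each: total counts
equal inner-join cardinality; nearest distance is 0 exactly when an
overlap or touch exists; coverage is bounded by probe length; exact
tiling gives fraction 1. Coordinate-system invariance is checked by
joining the same data in both representations. A scale test joins 10⁶
against 10⁶ generated intervals eagerly and streamed and requires
identical output; these sizes keep the whole suite around two minutes on
one CPU while exercising the index decomposition and the streaming path
at realistic volume.

`iv_merge()` deserves one note: it returns the minimal disjoint sorted
set covering the input union, merging book-ended intervals at
`min_gap = 0` and intervals separated by fewer than `min_gap` bases
otherwise. Payload columns are dropped (a merged interval has no single
source row) and zero-length spans are dropped too — they contribute no
bases, so the union is unchanged; callers who need them keep them in the
original frame. Merging is idempotent, and the bitmap oracle confirms
base-for-base agreement.

# Known limitations

* No strand-aware algebra: joins ignore strand columns (they pass through
  as payload).
* No contig-length bounds checking against an assembly (`.fai` /
  `chrom.sizes`); intervals are validated internally consistent only.
* No BAM/FASTQ/FASTA readers and no tabix index support — binary and
  sequence formats are orthogonal to the interval engine.
* Single-threaded: the contracts (multiset equality, bounded retention)
  are written so a parallel executor could be added without API change,
  but none ships.
* `subtract`, `complement`, reciprocal-overlap thresholds and group-wise
  joins are not provided; the four operations here are the load-bearing
  primitives the rest can be built from.
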