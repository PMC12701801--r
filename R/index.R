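#' Build an augmented-interval-list index
#'
#' Builds an immutable per-contig search structure over the build side of
#' a join: intervals are sorted by start and annotated with a running
#' maximum of end positions, so an overlap query is a binary search on
#' start followed by a backward scan that stops as soon as the running
#' maximum falls below the query start. When many long, containing
#' intervals would defeat that pruning, the list is decomposed into a
#' small number of length-partitioned components (an augmented interval
#' list), each scanned the same way.
#'
#' Queries run in the canonical half-open system; a frame tagged
#' 1-based closed is converted on entry and the tag recorded.
#'
#' @inheritParams iv_validate
#' @return An `iv_index` object.
#' @examples
#' idx <- iv_index(tibble::tibble(chrom = "chr1",
#'                                start = c(0, 15), end = c(10, 20)))
#' iv_query_overlaps(idx, "chr1", 5, 16)
#' @export
iv_index <- function(x, coords = NULL) {
  check_iv_columns(x)
  source_coords <- resolve_coords(x, coords)
  bad <- iv_validate(x, source_coords)
  if (nrow(bad) > 0) abort_violations(bad)
  h <- iv_convert(set_coords(as_tibble(x), source_coords),
                  "zero_based_half_open")
  groups <- split(seq_len(nrow(h)), h$chrom)
  contigs <- lapply(groups, function(rows) {
    node <- rk_build(h$start[rows], h$end[rows])
    list(node = node, rows = rows)
  })
  structure(
    list(contigs = contigs, n_items = nrow(h),
         source_coords = source_coords, frame = h),
    class = "iv_index")
}

#' @export
print.iv_index <- function(x, ...) {
  cat("<iv_index> ", x$n_items, " intervals over ",
      length(x$contigs), " contig(s)\n", sep = "")
  invisible(x)
}

#' @describeIn iv_index Per-contig summary: interval count and number of
#'   augmented-list components.
#' @param ... Unused.
#' @export
tidy.iv_index <- function(x, ...) {
  tibble(
    chrom = names(x$contigs),
    n = vapply(x$contigs, function(ct) length(ct$rows), integer(1)),
    n_components = vapply(x$contigs,
                          function(ct) length(ct$node$comp_lo), integer(1)))
}

#' @describeIn iv_index One-row summary of the whole index.
#' @export
glance.iv_index <- function(x, ...) {
  tibble(n_items = x$n_items, n_contigs = length(x$contigs),
         source_coords = x$source_coords)
}

# Batched query against the index for a probe tibble already in half-open
# coordinates. Returns 1-based probe row positions paired with build frame
# row numbers, per-probe overlap counts, and the instrumented count of
# list entries inspected per probe.
index_query <- function(idx, probe, count_only = FALSE) {
  nq <- nrow(probe)
  counts <- integer(nq)
  ncand <- numeric(nq)
  qrows <- numeric(0)
  brows <- numeric(0)
  for (chrom in intersect(unique(probe$chrom), names(idx$contigs))) {
    sel <- which(probe$chrom == chrom)
    ct <- idx$contigs[[chrom]]
    res <- rk_query(ct$node, probe$start[sel], probe$end[sel], count_only)
    counts[sel] <- res$count
    ncand[sel] <- res$ncand
    if (!count_only && length(res$q_idx) > 0) {
      qrows <- c(qrows, sel[res$q_idx])
      brows <- c(brows, ct$rows[res$b_idx])
    }
  }
  list(q = qrows, b = brows, counts = counts, ncand = ncand)
}

index_nearest <- function(idx, probe, k = 1) {
  qrows <- numeric(0)
  brows <- numeric(0)
  dists <- numeric(0)
  for (chrom in intersect(unique(probe$chrom), names(idx$contigs))) {
    sel <- which(probe$chrom == chrom)
    ct <- idx$contigs[[chrom]]
    res <- rk_nearest(ct$node, as.numeric(ct$rows),
                      probe$start[sel], probe$end[sel], as.integer(k))
    if (length(res$q_idx) > 0) {
      qrows <- c(qrows, sel[res$q_idx])
      brows <- c(brows, ct$rows[res$b_idx])
      dists <- c(dists, res$dist)
    }
  }
  list(q = qrows, b = brows, dist = dists)
}

#' Query an interval index
#'
#' Point-of-use queries against an [iv_index()]: `iv_query_overlaps()`
#' returns the build-frame row numbers whose intervals overlap the query,
#' `iv_count_overlaps_point()` just their number, and `iv_query_nearest()`
#' the `k` closest build rows with their distances. In half-open
#' coordinates two intervals overlap iff they share at least one base
#' (`b.start < q.end && q.start < b.end`); a zero-length span `(p, p)` is
#' treated as the point `p`, overlapping `[s, e)` iff `s <= p < e`.
#' Distance is `max(0, b.start - q.end, q.start - b.end)`: the gap in
#' bases, 0 for overlapping *or* book-ended (touching) intervals — note
#' touching intervals have distance 0 yet do not overlap. Nearest ties
#' are broken by smaller build start, then end, then row number.
#'
#' @param idx An [iv_index()].
#' @param chrom,start,end The query interval, in the index's source
#'   coordinate system. An unknown contig yields no hits.
#' @param k Number of nearest rows to return (distinct rows, not distinct
#'   distances).
#' @return `iv_query_overlaps()`: an integer vector of build row numbers
#'   (order unspecified). `iv_count_overlaps_point()`: a count.
#'   `iv_query_nearest()`: a tibble with `row` and `distance`, distances
#'   non-decreasing; zero rows if the contig is absent.
#' @export
iv_query_overlaps <- function(idx, chrom, start, end) {
  q <- query_frame(idx, chrom, start, end)
  sort(as.integer(index_query(idx, q)$b))
}

#' @rdname iv_query_overlaps
#' @export
iv_count_overlaps_point <- function(idx, chrom, start, end) {
  q <- query_frame(idx, chrom, start, end)
  index_query(idx, q, count_only = TRUE)$counts[1]
}

#' @rdname iv_query_overlaps
#' @export
iv_query_nearest <- function(idx, chrom, start, end, k = 1) {
  stopifnot(k >= 1)
  q <- query_frame(idx, chrom, start, end)
  res <- index_nearest(idx, q, k)
  tibble(row = as.integer(res$b), distance = res$dist)
}

query_frame <- function(idx, chrom, start, end) {
  q <- iv_frame(tibble(chrom = chrom, start = start, end = end),
                coords = idx$source_coords)
  iv_convert(q, "zero_based_half_open")
}
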