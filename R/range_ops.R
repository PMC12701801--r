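RK_OPS <- c("overlap", "nearest", "count_overlaps", "coverage")

# ---------------------------------------------------------------------------
# Shared execution core. A range operation is split into:
#   * op_state():   everything derived from the build side b alone —
#                   the interval index (or, for coverage, the merged union
#                   table per contig). Built once, reused across probe chunks.
#   * op_finalize(): the pieces that depend on the caller's coordinate
#                   system (the suffixed build-side output columns).
#   * op_chunk():   maps one probe chunk to its output rows.
# Eager calls run one chunk; the streaming executor loops.
# ---------------------------------------------------------------------------

op_state <- function(op, b, how = "inner", suffixes = c("_1", "_2"), k = 1) {
  op <- match.arg(op, RK_OPS)
  how <- match.arg(how, c("inner", "left"))
  stopifnot(length(suffixes) == 2, is.character(suffixes),
            suffixes[1] != suffixes[2], k >= 1)
  check_iv_columns(b)
  b_coords <- resolve_coords(b)
  bad <- iv_validate(b, b_coords)
  if (nrow(bad) > 0) abort_violations(bad)
  b <- set_coords(as_tibble(b), b_coords)
  st <- list(op = op, how = how, suffixes = suffixes, k = k,
             b = b, b_coords = b_coords, n_build = nrow(b))
  if (op == "coverage") {
    merged <- iv_merge(iv_convert(b, "zero_based_half_open"))
    st$cov <- lapply(split(merged, merged$chrom), function(m) {
      list(ms = m$start, me = m$end, cum = cumsum(m$end - m$start))
    })
  } else {
    st$idx <- iv_index(b)
  }
  st
}

op_finalize <- function(st, caller_coords) {
  st$caller_coords <- caller_coords
  if (st$op %in% c("overlap", "nearest")) {
    b_out <- iv_convert(st$b, caller_coords)
    st$b_out <- rename_with(as_tibble(b_out), ~ paste0(.x, st$suffixes[2]))
  }
  st
}

# chunk: probe rows in the caller's coordinate system, already validated
op_chunk <- function(st, chunk) {
  ch <- iv_convert(set_coords(as_tibble(chunk), st$caller_coords),
                   "zero_based_half_open")
  a_out <- rename_with(as_tibble(chunk), ~ paste0(.x, st$suffixes[1]))
  switch(st$op,
    overlap = {
      res <- index_query(st$idx, ch)
      q <- res$q
      b <- res$b
      if (st$how == "left") {
        miss <- setdiff(seq_len(nrow(ch)), q)
        q <- c(q, miss)
        b <- c(b, rep(NA_real_, length(miss)))
      }
      o <- order(q, ifelse(is.na(b), Inf, b))
      bind_cols(a_out[q[o], ], st$b_out[b[o], ])
    },
    nearest = {
      res <- index_nearest(st$idx, ch, st$k)
      o <- order(res$q)  # stable: keeps per-probe tie-break order
      q <- res$q[o]
      b <- res$b[o]
      d <- res$dist[o]
      miss <- setdiff(seq_len(nrow(ch)), q)
      q <- c(q, miss)
      b <- c(b, rep(NA_real_, length(miss)))
      d <- c(d, rep(NA_real_, length(miss)))
      o2 <- order(q, ifelse(is.na(d), Inf, d))
      # order() on (q, d) alone is stable, so equal-distance ties keep
      # the (start, end, row) order produced by the index
      bind_cols(a_out[q[o2], ], st$b_out[b[o2], ],
                tibble(distance = d[o2]))
    },
    count_overlaps = {
      counts <- index_query(st$idx, ch, count_only = TRUE)$counts
      bind_cols(a_out, tibble(count = as.integer(counts)))
    },
    coverage = {
      covered <- coverage_chunk(st$cov, ch)
      len <- ch$end - ch$start
      frac <- ifelse(len == 0, 0, covered / len)
      bind_cols(a_out, tibble(covered = covered, coverage_fraction = frac))
    })
}

coverage_chunk <- function(cov, ch) {
  covered <- numeric(nrow(ch))
  for (chrom in intersect(unique(ch$chrom), names(cov))) {
    sel <- which(ch$chrom == chrom)
    tb <- cov[[chrom]]
    covered[sel] <- cov_before(tb, ch$end[sel]) - cov_before(tb, ch$start[sel])
  }
  covered
}

# total merged bases strictly below position p (vectorized over p)
cov_before <- function(tb, p) {
  j <- findInterval(p, tb$ms)
  out <- numeric(length(p))
  hit <- j > 0
  out[hit] <- tb$cum[j[hit]] - pmax(0, tb$me[j[hit]] - p[hit])
  out
}

op_eager <- function(op, a, b, how = "inner", suffixes = c("_1", "_2"),
                     k = 1, sort_output = TRUE) {
  check_iv_columns(a)
  caller <- resolve_coords(a)
  bad <- iv_validate(a, caller)
  if (nrow(bad) > 0) abort_violations(bad)
  st <- op_finalize(op_state(op, b, how = how, suffixes = suffixes, k = k),
                    caller)
  out <- op_chunk(st, set_coords(as_tibble(a), caller))
  attr(out, "iv_coords") <- caller
  attr(out, "rk_op") <- op
  out
}

#' Overlap join of two interval frames
#'
#' Pairs every interval of the probe frame `a` with every interval of the
#' build frame `b` that overlaps it on the same contig (shares at least
#' one base; book-ended intervals do not overlap). `b` is indexed (the
#' build side), `a` is scanned against the index (the probe side). The
#' two frames may use different coordinate systems; output coordinates
#' are reported in `a`'s system.
#'
#' @param a Probe frame: tibble with `chrom`, `start`, `end` and payload
#'   columns, optionally tagged by [iv_frame()] (untagged frames are
#'   taken as 0-based half-open).
#' @param b Build frame, same shape.
#' @param how `"inner"` emits one row per overlapping pair; `"left"`
#'   additionally emits one row per unmatched `a` interval with `NA`
#'   build-side columns.
#' @param suffixes Length-2 character vector appended to probe- and
#'   build-side column names.
#' @param sort_output Order rows by (probe row, build row). Results are
#'   produced in this order in any case; the flag documents the contract
#'   for executions (e.g. streamed or parallel) free to relax it.
#' @return A tibble with `a`'s columns suffixed `suffixes[1]`, `b`'s
#'   suffixed `suffixes[2]`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 149, end = 250)
#' b <- tibble::tibble(chrom = "chr1", start = c(99, 299), end = c(200, 400))
#' iv_overlap(a, b)
#' @export
iv_overlap <- function(a, b, how = c("inner", "left"),
                       suffixes = c("_1", "_2"), sort_output = TRUE) {
  how <- match.arg(how)
  op_eager("overlap", a, b, how = how, suffixes = suffixes,
           sort_output = sort_output)
}

#' Nearest-feature join
#'
#' For every interval of `a`, finds the `k` intervals of `b` on the same
#' contig that overlap it or lie closest to it. Distance is the gap in
#' half-open coordinates, `max(0, b.start - a.end, a.start - b.end)`:
#' zero for overlapping or touching intervals. Every `a` row appears in
#' the output; if `b` has fewer than `k` rows on the contig, fewer
#' matches are emitted, and an `a` interval on a contig absent from `b`
#' yields a single row with `NA` build columns and `NA` distance. Ties at
#' equal distance go to the smaller build start, then end, then row
#' number; per probe, distances are non-decreasing.
#'
#' @inheritParams iv_overlap
#' @param k Number of nearest build rows per probe row (distinct rows,
#'   not distinct distances).
#' @return A tibble as in [iv_overlap()] plus a `distance` column (base
#'   pairs).
#' @export
iv_nearest <- function(a, b, k = 1, suffixes = c("_1", "_2"),
                       sort_output = TRUE) {
  op_eager("nearest", a, b, k = k, suffixes = suffixes,
           sort_output = sort_output)
}

#' Count overlapping intervals
#'
#' For every interval of `a`, counts the intervals of `b` overlapping it.
#' Exactly `nrow(a)` rows are returned, in `a`'s row order, with a
#' `count` column (zero included; duplicated `b` rows each count).
#'
#' @inheritParams iv_overlap
#' @return A tibble with `a`'s columns suffixed `suffixes[1]` and an
#'   integer `count` column.
#' @export
iv_count_overlaps <- function(a, b, suffixes = c("_1", "_2")) {
  op_eager("count_overlaps", a, b, suffixes = suffixes)
}

#' Per-interval coverage
#'
#' For every interval of `a`, the number of its bases covered by the
#' union of `b` (stacked `b` intervals never double-count: coverage is
#' computed against [iv_merge()] of `b`). Exactly `nrow(a)` rows in `a`'s
#' order with `covered` (base pairs, between 0 and the interval length)
#' and `coverage_fraction` (`covered / length`, defined as 0 for a
#' zero-length probe).
#'
#' @inheritParams iv_overlap
#' @return A tibble with `a`'s columns suffixed `suffixes[1]` plus
#'   `covered` and `coverage_fraction`.
#' @examples
#' a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
#' b <- tibble::tibble(chrom = "chr1", start = c(2, 4), end = c(5, 8))
#' iv_coverage(a, b)
#' @export
iv_coverage <- function(a, b, suffixes = c("_1", "_2")) {
  op_eager("coverage", a, b, suffixes = suffixes)
}
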