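#' Coordinate systems
#'
#' rangekit supports the two interval conventions used by the standard
#' genomic text formats:
#'
#' * `"zero_based_half_open"` — BED convention: an interval `[start, end)`
#'   contains positions `start <= p < end`; its length is `end - start` and
#'   `start == end` is a valid zero-length (point-like) span.
#' * `"one_based_closed"` — GFF3/VCF convention: an interval `start..end`
#'   contains both endpoints; `start >= 1` and zero-length spans have no
#'   representation.
#'
#' Every interval frame carries its system as an attribute (see
#' [iv_frame()]); all operations convert to half-open coordinates
#' internally, where interval arithmetic needs no off-by-one corrections,
#' and restore the caller's system on output.
#'
#' @name coordinate-systems
NULL

COORD_SYSTEMS <- c("zero_based_half_open", "one_based_closed")

IV_COLS <- c("chrom", "start", "end")

#' Tag a data frame as an interval frame
#'
#' An interval frame is an ordinary tibble with designated coordinate
#' columns `chrom` (contig name, compared by exact string equality),
#' `start` and `end` (base pairs, whole numbers), any number of payload
#' columns carried through operations unchanged, and a coordinate-system
#' attribute. Row `i` of the frame is implicitly interval number `i`
#' (its row id), stable under reading and batching.
#'
#' @param x A data frame with `chrom`, `start`, `end` columns.
#' @param coords Coordinate system of `x`; see [coordinate-systems].
#' @param validate Check the row-wise interval invariants (default `TRUE`).
#' @return `x` as a tibble tagged with the coordinate system.
#' @examples
#' iv_frame(tibble::tibble(chrom = "chr1", start = 0, end = 100))
#' @export
iv_frame <- function(x, coords = c("zero_based_half_open", "one_based_closed"),
                     validate = TRUE) {
  coords <- match.arg(coords)
  check_iv_columns(x)
  x <- as_tibble(x)
  attr(x, "iv_coords") <- coords
  if (validate) {
    bad <- iv_validate(x)
    if (nrow(bad) > 0) abort_violations(bad)
  }
  x
}

#' @rdname iv_frame
#' @export
iv_coords <- function(x) attr(x, "iv_coords", exact = TRUE)

resolve_coords <- function(x, coords = NULL) {
  cs <- coords %||% iv_coords(x) %||% "zero_based_half_open"
  match.arg(cs, COORD_SYSTEMS)
}

set_coords <- function(x, coords) {
  attr(x, "iv_coords") <- coords
  x
}

check_iv_columns <- function(x) {
  if (!is.data.frame(x)) {
    abort("`x` must be a data frame of intervals.",
          class = "rangekit_structure_error")
  }
  missing_cols <- setdiff(IV_COLS, names(x))
  if (length(missing_cols) > 0) {
    abort(paste0("Missing coordinate column(s): ",
                 paste(missing_cols, collapse = ", ")),
          class = "rangekit_structure_error")
  }
  if (!is.numeric(x$start) || !is.numeric(x$end)) {
    abort("`start` and `end` must be numeric (whole numbers).",
          class = "rangekit_structure_error")
  }
  invisible(x)
}

abort_violations <- function(bad) {
  shown <- utils::head(bad, 5)
  msg <- paste0("Invalid interval frame (", nrow(bad), " violation",
                if (nrow(bad) > 1) "s" else "", "):\n",
                paste0("  row ", shown$row_id, ": ", shown$reason,
                       collapse = "\n"))
  abort(msg, class = "rangekit_validation_error", violations = bad)
}

#' Validate an interval frame
#'
#' Checks every row against the invariants of the frame's coordinate
#' system and returns one record per violation (an empty tibble means the
#' frame is valid). Structural problems — missing coordinate columns,
#' non-numeric coordinates — raise an error instead of being reported
#' row-wise.
#'
#' @inheritParams iv_frame
#' @param coords Coordinate system to validate against; defaults to the
#'   frame's own tag, or half-open for an untagged frame.
#' @return A tibble with columns `row_id` (row number) and `reason`.
#' @examples
#' iv_validate(tibble::tibble(chrom = "chr1", start = 10, end = 5))
#' @export
iv_validate <- function(x, coords = NULL) {
  check_iv_columns(x)
  coords <- resolve_coords(x, coords)
  s <- x$start
  e <- x$end
  rid <- seq_len(nrow(x))
  out <- list()
  miss <- is.na(x$chrom) | is.na(s) | is.na(e)
  out$missing <- tibble(row_id = rid[miss],
                        reason = "missing chrom/start/end value")
  frac <- !miss & (s %% 1 != 0 | e %% 1 != 0)
  out$frac <- tibble(row_id = rid[frac],
                     reason = "non-integer coordinate")
  ok <- !miss & !frac
  min_start <- if (coords == "one_based_closed") 1 else 0
  low <- ok & s < min_start
  out$low <- tibble(row_id = rid[low],
                    reason = paste0("start < ", min_start))
  inv <- ok & !low & s > e
  out$inv <- tibble(row_id = rid[inv], reason = "start > end")
  res <- bind_rows(out)
  res[order(res$row_id), ]
}

#' Convert an interval frame between coordinate systems
#'
#' Maps `one_based_closed` coordinates `(start, end)` to half-open
#' `(start - 1, end)` and back; converting to the system a frame is
#' already in is the identity, and a round trip restores the original
#' coordinates exactly. Payload columns are untouched.
#'
#' A zero-length half-open interval (`start == end`) has no 1-based
#' closed representation; converting one is an error.
#'
#' @inheritParams iv_validate
#' @param to Target coordinate system.
#' @return The converted frame, tagged with `to`.
#' @examples
#' x <- iv_frame(tibble::tibble(chrom = "chr1", start = 1, end = 10),
#'               coords = "one_based_closed")
#' iv_convert(x, "zero_based_half_open")
#' @export
iv_convert <- function(x, to = c("zero_based_half_open", "one_based_closed"),
                       coords = NULL) {
  to <- match.arg(to)
  check_iv_columns(x)
  from <- resolve_coords(x, coords)
  x <- as_tibble(x)
  if (from == to) return(set_coords(x, to))
  if (from == "one_based_closed") {
    x$start <- x$start - 1
  } else {
    zero_len <- !is.na(x$start) & !is.na(x$end) & x$start == x$end
    if (any(zero_len)) {
      abort(paste0("Zero-length half-open interval(s) at row(s) ",
                   paste(utils::head(which(zero_len), 5), collapse = ", "),
                   " have no one_based_closed representation."),
            class = "rangekit_validation_error")
    }
    x$start <- x$start + 1
  }
  set_coords(x, to)
}

#' Sort an interval frame
#'
#' Orders rows by contig name (lexicographic, C locale), then `start`,
#' then `end`; the sort is stable, so rows with identical coordinates
#' keep their original relative order and payload moves with its row.
#'
#' @inheritParams iv_validate
#' @return The sorted frame (same rows, same attributes).
#' @export
iv_sort <- function(x) {
  check_iv_columns(x)
  cs <- iv_coords(x)
  out <- arrange(as_tibble(x), .data$chrom, .data$start, .data$end)
  if (!is.null(cs)) out <- set_coords(out, cs)
  out
}

#' Merge overlapping intervals
#'
#' Returns, per contig, the minimal sorted set of disjoint intervals whose
#' union of bases equals the input's. With `min_gap = 0`, overlapping and
#' book-ended (touching) intervals merge; with `min_gap > 0`, intervals
#' separated by fewer than `min_gap` bases merge as well. Merging is
#' idempotent. Payload columns are dropped (a merged interval has no
#' single source row) and zero-length spans, which contribute no bases,
#' are dropped too.
#'
#' @inheritParams iv_validate
#' @param min_gap Merge intervals separated by fewer than this many bases
#'   (non-negative; default 0).
#' @return A tibble of disjoint `chrom`/`start`/`end` rows in the caller's
#'   coordinate system.
#' @examples
#' x <- tibble::tibble(chrom = "chr1", start = c(1, 4, 10), end = c(5, 8, 12))
#' iv_merge(x)
#' @export
iv_merge <- function(x, min_gap = 0, coords = NULL) {
  stopifnot(is.numeric(min_gap), length(min_gap) == 1, min_gap >= 0)
  check_iv_columns(x)
  caller <- resolve_coords(x, coords)
  bad <- iv_validate(x, caller)
  if (nrow(bad) > 0) abort_violations(bad)
  h <- iv_convert(set_coords(as_tibble(x), caller), "zero_based_half_open")
  h <- h[h$end > h$start, IV_COLS]
  if (nrow(h) == 0) {
    out <- tibble(chrom = character(), start = numeric(), end = numeric())
    return(set_coords(out, caller))
  }
  h <- arrange(h, .data$chrom, .data$start, .data$end)
  out <- h |>
    group_by(.data$chrom) |>
    mutate(.gap = .data$start - cummax_lag(.data$end),
           .grp = cumsum(.data$.gap >= max(1, min_gap))) |>
    group_by(.data$chrom, .data$.grp) |>
    summarise(start = min(.data$start), end = max(.data$end),
              .groups = "drop")
  out <- arrange(out[IV_COLS], .data$chrom, .data$start)
  set_coords(iv_convert(set_coords(out, "zero_based_half_open"), caller), caller)
}

# running max of previous ends; -Inf before the first interval of a contig
cummax_lag <- function(e) {
  c(-Inf, cummax(e)[-length(e)])
}

iv_length <- function(start, end) end - start
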