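#' Batch iterator over an in-memory interval frame
#'
#' Slices a frame into contiguous batches of at most `batch_size` rows.
#' The returned function yields, per call, a list with `data` (the rows,
#' keeping the frame's coordinate tag), `batch_index` (1-based), and
#' `is_last`; after the last batch it yields `NULL`. Concatenating the
#' batches in order reconstructs the frame exactly.
#'
#' @inheritParams iv_validate
#' @param batch_size Maximum rows per batch (>= 1).
#' @return A zero-argument iterator function.
#' @export
iv_batches <- function(x, batch_size = 65536) {
  stopifnot(batch_size >= 1)
  x <- as_tibble(x)
  cs <- iv_coords(x)
  n <- nrow(x)
  starts <- seq(1, max(n, 1), by = batch_size)
  if (n == 0) starts <- integer(0)
  i <- 0L
  function() {
    i <<- i + 1L
    if (i > length(starts)) return(NULL)
    lo <- starts[i]
    hi <- min(lo + batch_size - 1, n)
    dat <- x[lo:hi, ]
    if (!is.null(cs)) dat <- set_coords(dat, cs)
    list(data = dat, batch_index = i, is_last = i == length(starts))
  }
}

#' Streamed (out-of-core) execution of a range operation
#'
#' Runs any of the four range operations with the probe side consumed as
#' a sequence of bounded batches: only the build side `b` is materialized
#' (as its index, or merged union for coverage), and at any moment at
#' most one probe batch plus its output batch is held. Concatenated
#' output batches equal the in-memory result of the same operation; each
#' batch's output is produced (and written to `sink`, if given) as soon
#' as that batch is processed. All four operations are per-probe-row, so
#' no probe-side global state is needed.
#'
#' @param op One of `"overlap"`, `"nearest"`, `"count_overlaps"`,
#'   `"coverage"`.
#' @param b Build frame (see [iv_overlap()]).
#' @param probe Probe side: a data frame (chunked via [iv_batches()]) or
#'   a batch iterator such as [iv_scan()] returns.
#' @param batch_size Rows per batch when `probe` is a data frame.
#' @param sink Optional output path; each output batch is appended as
#'   TSV/CSV as it is produced (header once).
#' @param sink_format `"tsv"` or `"csv"`.
#' @param collect Accumulate and return the combined result (default:
#'   yes unless a `sink` is given; with `collect = FALSE` memory stays
#'   bounded regardless of output size).
#' @param on_batch Optional callback `function(result, batch_index)`
#'   invoked with each output batch as soon as it is available.
#' @param ... Operation parameters: `how`, `suffixes`, `k`.
#' @return The combined result tibble (if `collect`), with an attribute
#'   `"stream_stats"` — a list with `n_batches`, `rows_in`, `rows_out`,
#'   and `max_probe_rows_retained` (the instrumented peak number of probe
#'   rows held, never exceeding the batch size). If `collect = FALSE`,
#'   the stats list invisibly.
#' @examples
#' a <- iv_generate(100, seed = 1)
#' b <- iv_generate(100, seed = 2)
#' out <- iv_stream("overlap", b, a, batch_size = 16)
#' attr(out, "stream_stats")$n_batches
#' @export
iv_stream <- function(op, b, probe, batch_size = 65536, sink = NULL,
                      sink_format = c("tsv", "csv"), collect = is.null(sink),
                      on_batch = NULL, ...) {
  op <- match.arg(op, RK_OPS)
  sink_format <- match.arg(sink_format)
  stopifnot(batch_size >= 1)
  it <- if (is.data.frame(probe)) iv_batches(probe, batch_size) else probe
  stopifnot(is.function(it))
  st <- op_state(op, b, ...)
  finalized <- FALSE
  header_written <- FALSE
  chunks <- list()
  stats <- list(n_batches = 0L, rows_in = 0, rows_out = 0,
                max_probe_rows_retained = 0)
  if (!is.null(sink)) file.create(sink)
  repeat {
    batch <- it()
    if (is.null(batch)) break
    chunk <- as_tibble(batch$data)
    caller <- resolve_coords(chunk)
    if (!finalized) {
      st <- op_finalize(st, caller)
      finalized <- TRUE
    }
    bad <- iv_validate(chunk, st$caller_coords)
    if (nrow(bad) > 0) abort_violations(bad)
    stats$n_batches <- stats$n_batches + 1L
    stats$rows_in <- stats$rows_in + nrow(chunk)
    stats$max_probe_rows_retained <-
      max(stats$max_probe_rows_retained, nrow(chunk))
    out <- op_chunk(st, set_coords(chunk, st$caller_coords))
    stats$rows_out <- stats$rows_out + nrow(out)
    if (!is.null(sink)) {
      write_table(out, sink, format = sink_format,
                  append = header_written, col_names = !header_written)
      header_written <- TRUE
    }
    if (!is.null(on_batch)) on_batch(out, batch$batch_index)
    if (collect) chunks[[length(chunks) + 1L]] <- out
  }
  if (collect) {
    res <- bind_rows(chunks)
    attr(res, "stream_stats") <- stats
    attr(res, "rk_op") <- op
    res
  } else {
    invisible(stats)
  }
}
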