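#' Plot an interval frame
#'
#' Draws intervals as horizontal segments per contig, greedily packed
#' into non-overlapping lanes — a quick look at density and clustering
#' for small frames.
#'
#' @inheritParams iv_validate
#' @param max_rows Downsample to at most this many intervals.
#' @return A ggplot object.
#' @export
plot_intervals <- function(x, max_rows = 5000) {
  check_iv_columns(x)
  h <- iv_convert(as_tibble(x), "zero_based_half_open",
                  coords = resolve_coords(x))
  if (nrow(h) > max_rows) h <- h[seq_len(max_rows), ]
  h <- arrange(h, .data$chrom, .data$start, .data$end)
  h <- h |>
    group_by(.data$chrom) |>
    mutate(lane = pack_lanes(.data$start, .data$end)) |>
    ungroup()
  ggplot2::ggplot(h, ggplot2::aes(x = .data$start, xend = .data$end,
                                  y = .data$lane, yend = .data$lane)) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::facet_wrap(~chrom, ncol = 1, scales = "free") +
    ggplot2::labs(x = "position (bp)", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}

# first-fit lane assignment over start-sorted intervals
pack_lanes <- function(start, end) {
  lane_end <- numeric(0)
  lane <- integer(length(start))
  for (i in seq_along(start)) {
    free <- which(lane_end <= start[i])
    if (length(free) > 0) {
      lane[i] <- free[1]
      lane_end[free[1]] <- end[i]
    } else {
      lane_end <- c(lane_end, end[i])
      lane[i] <- length(lane_end)
    }
  }
  lane
}

#' Plot a coverage result
#'
#' Histogram of per-interval coverage fractions from [iv_coverage()].
#'
#' @param x A coverage join result.
#' @param bins Number of histogram bins.
#' @return A ggplot object.
#' @export
plot_coverage <- function(x, bins = 30) {
  if (!"coverage_fraction" %in% names(x)) {
    abort("`x` must be an iv_coverage() result with a coverage_fraction column.")
  }
  ggplot2::ggplot(x, ggplot2::aes(x = .data$coverage_fraction)) +
    ggplot2::geom_histogram(bins = bins, boundary = 0) +
    ggplot2::labs(x = "coverage fraction", y = "intervals") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
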