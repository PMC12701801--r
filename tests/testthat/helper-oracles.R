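# Independent brute-force oracles, deliberately naive: nested-loop scans
# for joins and per-base bitmaps for union/coverage. They share no code
# with the package's index path.

# half-open overlap predicate; zero-length spans behave as points
# ((p,p) overlaps [s,e) iff s <= p < e; two points never overlap)
hits_row <- function(as, ae, bs, be) {
  if (as == ae) return(bs <= as & as < be)
  zl <- bs == be
  out <- as < be & bs < ae
  out[zl] <- as <= bs[zl] & bs[zl] < ae
  out
}

# one row per overlapping (a_i, b_j) pair; frames in half-open coords
oracle_overlap_pairs <- function(a, b) {
  qs <- integer(0); bs <- integer(0)
  for (i in seq_len(nrow(a))) {
    same <- b$chrom == a$chrom[i]
    hit <- same & hits_row(a$start[i], a$end[i], b$start, b$end)
    j <- which(hit)
    qs <- c(qs, rep(i, length(j)))
    bs <- c(bs, j)
  }
  tibble::tibble(q = qs, b = bs)
}

oracle_counts <- function(a, b) {
  p <- oracle_overlap_pairs(a, b)
  tabulate(p$q, nbins = nrow(a))
}

# distance in half-open coords: gap in bases, 0 when overlapping/touching
oracle_dist <- function(as, ae, bs, be) pmax(0, bs - ae, as - be)

# min(k, n on contig) nearest rows per probe; ties by (start, end, row)
oracle_nearest <- function(a, b, k = 1) {
  out <- list()
  for (i in seq_len(nrow(a))) {
    j <- which(b$chrom == a$chrom[i])
    if (length(j) == 0) {
      out[[i]] <- tibble::tibble(q = i, b = NA_integer_, dist = NA_real_)
      next
    }
    d <- oracle_dist(a$start[i], a$end[i], b$start[j], b$end[j])
    o <- order(d, b$start[j], b$end[j], j)
    take <- o[seq_len(min(k, length(j)))]
    out[[i]] <- tibble::tibble(q = i, b = j[take], dist = d[take])
  }
  dplyr::bind_rows(out)
}

# per-base bitmap of the union of b, then per-probe covered bases
oracle_coverage <- function(a, b, max_coord = 1e5) {
  bases <- list()
  for (chrom in unique(b$chrom)) {
    bit <- logical(max_coord + 1)
    for (j in which(b$chrom == chrom)) {
      if (b$end[j] > b$start[j]) {
        bit[(b$start[j] + 1):b$end[j]] <- TRUE  # base p -> bit[p + 1]
      }
    }
    bases[[chrom]] <- bit
  }
  vapply(seq_len(nrow(a)), function(i) {
    bit <- bases[[a$chrom[i]]]
    if (is.null(bit) || a$end[i] == a$start[i]) return(0)
    sum(bit[(a$start[i] + 1):a$end[i]])
  }, numeric(1))
}

# union bitmap oracle for merge: membership vector per contig
oracle_union_bitmap <- function(x, max_coord = 1e5) {
  out <- list()
  for (chrom in unique(x$chrom)) {
    bit <- logical(max_coord + 1)
    for (j in which(x$chrom == chrom)) {
      if (x$end[j] > x$start[j]) bit[(x$start[j] + 1):x$end[j]] <- TRUE
    }
    out[[chrom]] <- bit
  }
  out
}

# seeded random instance: <= n_max rows per side, coords < coord_max,
# 1-3 contigs, unique payload ids; lengths include occasional zero-length
# spans unless zero_len = FALSE
rand_iv <- function(n, prefix, coord_max = 1e5, n_contigs = 3,
                    zero_len = TRUE, max_len = 300) {
  chroms <- paste0("chr", seq_len(n_contigs))
  start <- sample.int(coord_max - max_len, n, replace = TRUE) - 1
  len <- sample.int(max_len + 1, n, replace = TRUE) - as.integer(zero_len)
  tibble::tibble(chrom = sample(chroms, n, replace = TRUE),
                 start = as.numeric(start),
                 end = as.numeric(start + len),
                 id = paste0(prefix, seq_len(n)))
}

rand_instance <- function(seed, n_max = 500, zero_len = TRUE) {
  set.seed(seed)
  nc <- sample(1:3, 1)
  list(a = rand_iv(sample.int(n_max, 1), "a", n_contigs = nc,
                   zero_len = zero_len),
       b = rand_iv(sample.int(n_max, 1), "b", n_contigs = nc,
                   zero_len = zero_len))
}

# multiset equality of data frame rows
expect_same_rows <- function(x, y) {
  x <- plain(x)
  y <- plain(y)
  x <- x[do.call(order, x), , drop = FALSE]
  y <- y[do.call(order, y), , drop = FALSE]
  rownames(x) <- NULL
  rownames(y) <- NULL
  expect_equal(x, y)
}

# expected join tables from oracle pair lists, using the unique id payloads
expected_overlap_tbl <- function(a, b, pairs) {
  tibble::tibble(id_1 = a$id[pairs$q], id_2 = b$id[pairs$b])
}

# thin adapters over package internals for oracle comparison
index_query_pairs_for_test <- function(idx, a) {
  res <- rangekit:::index_query(idx, a)
  tibble::tibble(q = as.numeric(res$q), b = as.numeric(res$b))
}

nearest_for_test <- function(idx, a) {
  res <- rangekit:::index_nearest(idx, a, 1)
  d <- rep(NA_real_, nrow(a))
  bb <- rep(NA_real_, nrow(a))
  d[res$q] <- res$dist
  bb[res$q] <- res$b
  tibble::tibble(q = seq_len(nrow(a)), b = bb, dist = d)
}

collect_scan_for_test <- function(it) {
  got <- list()
  repeat {
    batch <- it()
    if (is.null(batch)) break
    got[[length(got) + 1]] <- batch$data
  }
  dplyr::bind_rows(got)
}

# data.frame with only structural attributes, for value comparisons
plain <- function(x) {
  x <- as.data.frame(x)
  attributes(x) <- attributes(x)[c("names", "class", "row.names")]
  x
}
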