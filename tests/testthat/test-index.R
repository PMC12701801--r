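test_that("index construction covers every row and answers self-queries", {
  empty <- iv_index(tibble::tibble(chrom = character(), start = numeric(),
                                   end = numeric()))
  expect_equal(empty$n_items, 0)
  expect_equal(iv_query_overlaps(empty, "chr1", 0, 100), integer(0))

  x <- tibble::tibble(chrom = "chr1", start = c(0, 15, 40), end = c(10, 20, 60))
  idx <- iv_index(x)
  expect_equal(idx$n_items, 3)
  for (i in seq_len(nrow(x))) {
    expect_true(i %in% iv_query_overlaps(idx, x$chrom[i], x$start[i], x$end[i]))
  }
  expect_equal(glance(idx)$n_contigs, 1)
  expect_equal(sum(tidy(idx)$n), 3)
})

test_that("overlap queries follow half-open semantics", {
  idx <- iv_index(tibble::tibble(chrom = "chr1", start = c(0, 15),
                                 end = c(10, 20)))
  expect_equal(iv_query_overlaps(idx, "chr1", 5, 16), c(1L, 2L))
  # unknown contig
  expect_equal(iv_query_overlaps(idx, "chr2", 0, 100), integer(0))
  # touching endpoints do not overlap
  expect_equal(iv_query_overlaps(idx, "chr1", 10, 15), integer(0))
  # counting agrees without materializing
  expect_equal(iv_count_overlaps_point(idx, "chr1", 5, 16), 2L)
  expect_equal(iv_count_overlaps_point(idx, "chr1", 10, 15), 0L)
})

test_that("duplicated build rows each count", {
  k <- 7
  idx <- iv_index(tibble::tibble(chrom = "chr1", start = rep(100, k),
                                 end = rep(200, k)))
  expect_equal(iv_count_overlaps_point(idx, "chr1", 150, 160), k)
  expect_equal(length(iv_query_overlaps(idx, "chr1", 150, 160)), k)
})

test_that("zero-length intervals behave as points on either side", {
  idx <- iv_index(tibble::tibble(chrom = "chr1", start = c(0, 10),
                                 end = c(10, 10)))
  # point probe inside [0,10)
  expect_equal(iv_query_overlaps(idx, "chr1", 5, 5), 1L)
  # point probe at the end boundary is outside
  expect_equal(iv_query_overlaps(idx, "chr1", 10, 10), integer(0))
  # zero-length build row at p = 10 is a point inside [10, 20) but not [5, 10)
  expect_equal(iv_query_overlaps(idx, "chr1", 10, 20), 2L)
  expect_equal(iv_query_overlaps(idx, "chr1", 5, 10), 1L)
})

test_that("nearest matches the worked example, overlaps, and tie-breaks", {
  idx <- iv_index(tibble::tibble(chrom = "chr1", start = c(0, 119),
                                 end = c(9, 130)))
  res <- iv_query_nearest(idx, "chr1", 99, 110)
  expect_equal(res$row, 2L)
  expect_equal(res$distance, 9)  # 119 - 110 = 9 < 99 - 9 = 90

  # overlapping build row has distance 0
  expect_equal(iv_query_nearest(idx, "chr1", 5, 20)$distance, 0)

  # equidistant candidates: smaller start wins
  idx2 <- iv_index(tibble::tibble(chrom = "chr1", start = c(0, 20),
                                  end = c(5, 25)))
  res <- iv_query_nearest(idx2, "chr1", 10, 15)
  expect_equal(res$row, 1L)
  expect_equal(res$distance, 5)

  # no build interval on the contig
  expect_equal(nrow(iv_query_nearest(idx, "chrX", 0, 10)), 0)
})

test_that("queries agree with the nested-loop oracle on random instances", {
  for (seed in 1:40) {
    inst <- rand_instance(seed, n_max = 200)
    idx <- iv_index(inst$b)
    pairs <- oracle_overlap_pairs(inst$a, inst$b)
    got <- index_query_pairs_for_test(idx, inst$a)
    expect_same_rows(got, pairs)
    # nearest distance equals brute-force minimum; zero iff overlap or touch
    nb <- oracle_nearest(inst$a, inst$b, k = 1)
    gn <- nearest_for_test(idx, inst$a)
    expect_equal(gn$dist, nb$dist)
    on_contig <- inst$a$chrom %in% inst$b$chrom
    touch_or_overlap <- vapply(seq_len(nrow(inst$a)), function(i) {
      j <- inst$b$chrom == inst$a$chrom[i]
      any(oracle_dist(inst$a$start[i], inst$a$end[i],
                      inst$b$start[j], inst$b$end[j]) == 0)
    }, logical(1))
    expect_equal(!is.na(gn$dist) & gn$dist == 0, touch_or_overlap)
    expect_true(all(is.na(gn$dist[!on_contig])))
  }
})

test_that("repeated identical queries return identical results", {
  set.seed(99)
  b <- rand_iv(300, "b")
  idx <- iv_index(b)
  r1 <- iv_query_overlaps(idx, "chr1", 1000, 5000)
  r2 <- iv_query_overlaps(idx, "chr1", 1000, 5000)
  expect_identical(r1, r2)
})

test_that("pruned scans inspect few candidates on sparse sorted data", {
  n <- 4096
  # disjoint tiled intervals with gaps; each probe overlaps exactly one
  b <- tibble::tibble(chrom = "chr1",
                      start = seq(0, by = 100, length.out = n),
                      end = seq(50, by = 100, length.out = n))
  idx <- iv_index(b)
  probe <- iv_convert(iv_frame(b[c("chrom", "start", "end")]),
                      "zero_based_half_open")
  res <- rangekit:::index_query(idx, probe)
  expect_equal(res$counts, rep(1L, n))
  expect_true(all(res$ncand <= 2 * (log2(n) + res$counts + 8)))
})

test_that("overlap pairs agree with IRanges as an independent cross-check", {
  for (seed in 1:10) {
    set.seed(seed)
    a <- rand_iv(150, "a", zero_len = FALSE)
    b <- rand_iv(150, "b", zero_len = FALSE)
    got <- iv_overlap(a, b)[c("id_1", "id_2")]
    exp <- list()
    for (chrom in union(a$chrom, b$chrom)) {
      ai <- which(a$chrom == chrom)
      bi <- which(b$chrom == chrom)
      if (length(ai) == 0 || length(bi) == 0) next
      # half-open [s, e) == 1-based closed (s + 1)..e
      ia <- IRanges::IRanges(a$start[ai] + 1, a$end[ai])
      ib <- IRanges::IRanges(b$start[bi] + 1, b$end[bi])
      hits <- IRanges::findOverlaps(ia, ib)
      exp[[chrom]] <- tibble::tibble(
        id_1 = a$id[ai[S4Vectors::queryHits(hits)]],
        id_2 = b$id[bi[S4Vectors::subjectHits(hits)]])
    }
    expect_same_rows(got, dplyr::bind_rows(exp))
  }
})
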