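test_that("overlap join: worked example, empty build side, self-join", {
  a <- tibble::tibble(chrom = "chr1", start = 149, end = 250, gene = "g1")
  b <- tibble::tibble(chrom = "chr1", start = c(99, 299), end = c(200, 400),
                      peak = c("p1", "p2"))
  out <- iv_overlap(a, b)
  expect_equal(nrow(out), 1)
  expect_equal(out$gene_1, "g1")
  expect_equal(out$peak_2, "p1")
  expect_equal(names(out), c("chrom_1", "start_1", "end_1", "gene_1",
                             "chrom_2", "start_2", "end_2", "peak_2"))

  empty_b <- b[0, ]
  expect_equal(nrow(iv_overlap(a, empty_b)), 0)
  left <- iv_overlap(a, empty_b, how = "left")
  expect_equal(nrow(left), nrow(a))
  expect_true(all(is.na(left$peak_2)))
  expect_equal(left$gene_1, a$gene)

  # disjoint set joined with itself: exactly the self pairs
  d <- tibble::tibble(chrom = "chr1", start = c(0, 100, 200),
                      end = c(50, 150, 250), id = c("x", "y", "z"))
  self <- iv_overlap(d, d)
  expect_equal(nrow(self), 3)
  expect_equal(self$id_1, self$id_2)
})

test_that("suffixes are configurable and resolve collisions", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 10, tag = "A")
  b <- tibble::tibble(chrom = "chr1", start = 5, end = 15, tag = "B")
  out <- iv_overlap(a, b, suffixes = c("_a", "_b"))
  expect_equal(out$tag_a, "A")
  expect_equal(out$tag_b, "B")
})

test_that("nearest join keeps every probe row and is left-style", {
  a <- tibble::tibble(chrom = c("chr1", "chrZ"), start = c(99, 5),
                      end = c(110, 10))
  b <- tibble::tibble(chrom = "chr1", start = c(0, 119), end = c(9, 130))
  out <- iv_nearest(a, b)
  expect_equal(nrow(out), 2)
  expect_equal(out$distance[1], 9)
  expect_equal(out$start_2[1], 119)
  # contig absent from b: single row, null match
  expect_true(is.na(out$distance[2]))
  expect_true(is.na(out$chrom_2[2]))

  # k = 2 with exactly 2 build rows: both returned, distances non-decreasing
  out2 <- iv_nearest(a[1, ], b, k = 2)
  expect_equal(nrow(out2), 2)
  expect_equal(out2$distance, sort(out2$distance))
  expect_equal(out2$distance, c(9, 90))
})

test_that("count_overlaps emits one row per probe, in probe order", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 100)
  b <- tibble::tibble(chrom = "chr1", start = c(10, 50, 200),
                      end = c(20, 60, 300))
  out <- iv_count_overlaps(a, b)
  expect_equal(out$count, 2L)
  expect_equal(iv_count_overlaps(a, b[0, ])$count, 0L)

  set.seed(11)
  aa <- rand_iv(80, "a")
  bb <- rand_iv(120, "b")
  expect_equal(iv_count_overlaps(aa, bb)$chrom_1, aa$chrom)
})

test_that("coverage counts union bases, never double-counting stacks", {
  a <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  b <- tibble::tibble(chrom = "chr1", start = c(2, 4), end = c(5, 8))
  out <- iv_coverage(a, b)
  expect_equal(out$covered, 6)  # bases 2..7
  expect_equal(out$coverage_fraction, 0.6)

  expect_equal(iv_coverage(a, b[0, ])$covered, 0)
  expect_equal(iv_coverage(a, b[0, ])$coverage_fraction, 0)

  # full cover: fraction exactly 1
  full <- iv_coverage(a, tibble::tibble(chrom = "chr1", start = 0, end = 10))
  expect_equal(full$covered, 10)
  expect_equal(full$coverage_fraction, 1)

  # zero-length probe: fraction defined as 0
  z <- iv_coverage(tibble::tibble(chrom = "chr1", start = 5, end = 5), b)
  expect_equal(z$coverage_fraction, 0)
})

test_that("all four operations agree with brute-force oracles on random instances", {
  for (seed in 1:40) {
    inst <- rand_instance(seed, n_max = 150)
    a <- inst$a
    b <- inst$b
    pairs <- oracle_overlap_pairs(a, b)
    got <- iv_overlap(a, b)
    expect_same_rows(got[c("id_1", "id_2")], expected_overlap_tbl(a, b, pairs))
    expect_equal(iv_count_overlaps(a, b)$count, oracle_counts(a, b))
    expect_equal(iv_coverage(a, b)$covered, oracle_coverage(a, b))
    nb <- oracle_nearest(a, b, k = 1)
    gn <- iv_nearest(a, b)
    expect_equal(gn$id_1, a$id)
    expect_equal(gn$distance, nb$dist)
    expect_equal(gn$id_2, ifelse(is.na(nb$b), NA_character_, b$id[nb$b]))
  }
})

test_that("sum of counts equals the inner-join cardinality", {
  for (seed in 101:110) {
    inst <- rand_instance(seed)
    expect_equal(sum(iv_count_overlaps(inst$a, inst$b)$count),
                 nrow(iv_overlap(inst$a, inst$b)))
  }
})

test_that("results are invariant to input row order", {
  set.seed(123)
  a <- rand_iv(120, "a")
  b <- rand_iv(150, "b")
  a2 <- a[sample(nrow(a)), ]
  b2 <- b[sample(nrow(b)), ]
  for (fn in list(iv_overlap,
                  function(x, y) iv_nearest(x, y, k = 2),
                  iv_count_overlaps, iv_coverage)) {
    expect_same_rows(fn(a, b), fn(a2, b2))
  }
})

test_that("results are invariant to the caller's coordinate system", {
  set.seed(7)
  a <- rand_iv(100, "a", zero_len = FALSE)
  b <- rand_iv(100, "b", zero_len = FALSE)
  a1 <- iv_convert(iv_frame(a), "one_based_closed")
  b1 <- iv_convert(iv_frame(b), "one_based_closed")
  # same joined pairs whichever representation is supplied
  h <- iv_overlap(a, b)
  o <- iv_overlap(a1, b1)
  expect_same_rows(h[c("id_1", "id_2")], o[c("id_1", "id_2")])
  # 1-based output is the converted coordinates of the half-open output
  expect_same_rows(
    dplyr::mutate(h, start_1 = start_1 + 1, start_2 = start_2 + 1),
    o)
  # mixed systems normalize internally
  m <- iv_overlap(a, b1)
  expect_same_rows(h[c("id_1", "id_2")], m[c("id_1", "id_2")])
  expect_equal(iv_coverage(a, b)$covered, iv_coverage(a1, b1)$covered)
  expect_equal(iv_nearest(a, b)$distance, iv_nearest(a1, b1)$distance)
})

test_that("payload columns pass through identically", {
  set.seed(5)
  a <- rand_iv(60, "a")
  a$meta <- replicate(60, paste(sample(letters, 8), collapse = ""))
  a$value <- rnorm(60)
  b <- rand_iv(80, "b")
  out <- iv_overlap(a, b, how = "left")
  first_hit <- !duplicated(out$id_1)
  m <- match(out$id_1[first_hit], a$id)
  expect_identical(out$meta_1[first_hit], a$meta[m])
  expect_identical(out$value_1[first_hit], a$value[m])
})

test_that("invalid frames are rejected with a violation report", {
  bad <- tibble::tibble(chrom = "chr1", start = 10, end = 5)
  ok <- tibble::tibble(chrom = "chr1", start = 0, end = 10)
  expect_error(iv_overlap(bad, ok), class = "rangekit_validation_error")
  expect_error(iv_overlap(ok, bad), class = "rangekit_validation_error")
})
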