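# rangekit

Fast genomic interval joins on tidy data frames.

Much of regulatory and clinical genomics reduces to relating two tables of
features laid out on chromosome coordinates: which peaks overlap which
genes, the nearest gene to each variant, how many reads fall in each bin,
what fraction of each exon is covered by a call set. `rangekit` is an
interval engine for exactly these questions, built for people who keep
their features in data frames: every operation takes ordinary tibbles with
`chrom`/`start`/`end` columns (plus any payload), returns a tibble, and
chains with the pipe. It comes with readers for BED, GFF3 and VCF, an
out-of-core streaming executor for probe tables too large for memory, a
deterministic synthetic-interval generator, and a small command-line
interface mirroring the R API.

## The operations and the index behind them

All arithmetic runs internally on half-open intervals `[s, e)` (the BED
convention); 1-based closed frames (GFF3/VCF) are converted on entry and
restored on output. For a probe interval *a* and build interval *b* on the
same contig:

* **overlap** — *a* and *b* overlap iff `b.start < a.end` and
  `a.start < b.end` (they share a base; book-ended intervals do not
  overlap). `iv_overlap()` emits one row per overlapping pair (`inner`) or
  additionally one row per unmatched probe (`left`).
* **nearest** — distance `d(a, b) = max(0, b.start − a.end, a.start − b.end)`,
  the gap in base pairs; 0 when the intervals overlap *or* touch.
  `iv_nearest()` returns the `k` closest build rows per probe, ties broken
  by smaller build start, then end, then row number.
* **count_overlaps** — `iv_count_overlaps()` returns, per probe row, the
  number of build rows overlapping it.
* **coverage** — `iv_coverage()` returns `|a ∩ ⋃B|`: the number of bases of
  *a* covered by the union of the build set (stacked intervals never
  double-count), plus the covered fraction of *a*'s length.

The build side of each operation is indexed with an augmented interval
list: per contig, intervals sorted by start and annotated with a running
maximum of end positions, so a query is a binary search on start followed
by a backward scan that stops as soon as the running maximum drops below
the query start. When long, containing intervals would blunt that pruning,
the list is decomposed into a small number of length-partitioned
components, each scanned the same way. Queries touch `O(log n + hits)`
entries on typical genomic data, and the index is immutable: in a join
only the build side is materialized, so the probe side can stream.

## A worked example

```r
library(rangekit)
library(tibble)

peaks <- tibble(chrom = "chr1", start = c(1150, 4100, 7900),
                end   = c(1450, 4550, 8200),
                peak  = c("p1", "p2", "p3"))
genes <- tibble(chrom = "chr1", start = c(1000, 5000),
                end   = c(2000, 6000),
                gene  = c("tp53", "brca2"))

iv_overlap(peaks, genes)
#> # A tibble: 1 × 8
#>   chrom_1 start_1 end_1 peak_1 chrom_2 start_2 end_2 gene_2
#>   <chr>     <dbl> <dbl> <chr>  <chr>     <dbl> <dbl> <chr>
#> 1 chr1       1150  1450 p1     chr1       1000  2000 tp53

iv_nearest(peaks, genes)
#> # A tibble: 3 × 9
#>   chrom_1 start_1 end_1 peak_1 chrom_2 start_2 end_2 gene_2 distance
#>   <chr>     <dbl> <dbl> <chr>  <chr>     <dbl> <dbl> <chr>     <dbl>
#> 1 chr1       1150  1450 p1     chr1       1000  2000 tp53          0
#> 2 chr1       4100  4550 p2     chr1       5000  6000 brca2       450
#> 3 chr1       7900  8200 p3     chr1       5000  6000 brca2      1900

iv_coverage(genes, peaks)
#> # A tibble: 2 × 6
#>   chrom_1 start_1 end_1 gene_1 covered coverage_fraction
#>   <chr>     <dbl> <dbl> <chr>    <dbl>             <dbl>
#> 1 chr1       1000  2000 tp53       300               0.3
#> 2 chr1       5000  6000 brca2        0               0
```

Reading p1 overlaps *tp53* (they share bases 1150–1449). p2's nearest gene
is *brca2*, 450 bp downstream; p1's distance is 0 because it overlaps.
*tp53* has 300 of its 1000 bases under a peak (fraction 0.3); *brca2* has
none. Probe columns carry the `_1` suffix, build columns `_2`
(configurable), and payload columns (`peak`, `gene`) ride along untouched.

File-based and out-of-core use follow the same shapes:

```r
variants <- read_vcf("cohort.vcf.gz")          # 1-based, REF-span intervals
genes    <- read_gff3("annotation.gff3")
iv_nearest(variants, genes)                    # coordinate systems normalize

# probe side streamed in bounded batches; only genes are materialized
iv_stream("count_overlaps", genes, iv_scan("huge.bed", batch_size = 65536),
          sink = "counts.tsv")
```

The same flows are available from a shell via the installed CLI wrapper
(`system.file("cli", "rangekit", package = "rangekit")`), e.g.
`rangekit overlap -a peaks.bed -b genes.gff3 --streaming -o out.tsv`.

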