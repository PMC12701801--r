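#' @title File formats
#' @description
#' rangekit reads the standard interval text formats into interval
#' frames, each tagged with the format's native coordinate system:
#' BED (0-based half-open), GFF3 and VCF (1-based closed), and TSV
#' frames previously written by [write_table()] (taken as half-open).
#' Gzip-compressed files are detected by magic bytes and decompressed
#' transparently. Line endings may be LF or CRLF.
#' @name file-formats
NULL

sniff_gzip <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", n = 2)
  length(magic) == 2 && magic[1] == as.raw(0x1f) && magic[2] == as.raw(0x8b)
}

open_text <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "rangekit_parse_error")
  }
  if (sniff_gzip(path)) gzfile(path, open = "rt") else file(path, open = "rt")
}

#' Detect an interval file format from its extension
#'
#' Recognizes `.bed`, `.gff3`/`.gff`, `.vcf` and `.tsv`, with a trailing
#' `.gz` peeled off first.
#'
#' @param path File path.
#' @return One of `"bed"`, `"gff3"`, `"vcf"`, `"tsv"`.
#' @export
detect_format <- function(path) {
  p <- sub("\\.gz$", "", path, ignore.case = TRUE)
  ext <- tolower(sub(".*\\.", "", basename(p)))
  switch(ext,
         bed = "bed", gff3 = "gff3", gff = "gff3", vcf = "vcf", tsv = "tsv",
         abort(paste0("Cannot detect format from extension: ", path),
               class = "rangekit_usage_error"))
}

parse_error <- function(path, line, msg) {
  abort(sprintf("%s:%d: %s", path, line, msg),
        class = "rangekit_parse_error", line = line)
}

fmt_coords <- function(format) {
  switch(format, bed = "zero_based_half_open", tsv = "zero_based_half_open",
         gff3 = "one_based_closed", vcf = "one_based_closed")
}

# ---------------------------------------------------------------------------
# Row parsers: character vector of data lines + their 1-based file line
# numbers -> tibble. Shared by the eager readers and the batch scanner, so
# eager read == concatenated scan by construction.
# ---------------------------------------------------------------------------

num_field <- function(x, nums, path, what) {
  v <- suppressWarnings(as.numeric(x))
  bad <- which(is.na(v) | v %% 1 != 0)
  if (length(bad) > 0) {
    parse_error(path, nums[bad[1]],
                paste0("non-integer ", what, ": '", x[bad[1]], "'"))
  }
  v
}

nth_field <- function(parts, j) {
  vapply(parts, function(p) if (length(p) >= j) p[[j]] else NA_character_,
         character(1))
}

BED_NAMES <- c("name", "score", "strand")

parse_bed_rows <- function(lines, nums, path) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 3)) {
    i <- which(nf < 3)[1]
    parse_error(path, nums[i], paste0("BED line has ", nf[i],
                                      " column(s); at least 3 required"))
  }
  out <- tibble(
    chrom = nth_field(parts, 1),
    start = num_field(nth_field(parts, 2), nums, path, "chromStart"),
    end = num_field(nth_field(parts, 3), nums, path, "chromEnd"))
  neg <- which(out$start < 0)
  if (length(neg) > 0) parse_error(path, nums[neg[1]], "negative chromStart")
  rev <- which(out$start > out$end)
  if (length(rev) > 0) {
    parse_error(path, nums[rev[1]],
                sprintf("chromStart (%s) > chromEnd (%s)",
                        format(out$start[rev[1]], scientific = FALSE),
                        format(out$end[rev[1]], scientific = FALSE)))
  }
  if (max(nf) >= 4) {
    for (j in 4:max(nf)) {
      nm <- if (j <= 6) BED_NAMES[j - 3] else paste0("col", j)
      val <- nth_field(parts, j)
      if (nm == "score") {
        iv <- suppressWarnings(as.integer(val))
        if (!anyNA(iv[!is.na(val)])) val <- iv
      }
      out[[nm]] <- val
    }
  }
  out
}

GFF3_EMPTY <- function() {
  tibble(chrom = character(), source = character(), type = character(),
         start = numeric(), end = numeric(), score = numeric(),
         strand = character(), phase = character(), attributes = character())
}

parse_gff3_rows <- function(lines, nums, path) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf != 9)) {
    i <- which(nf != 9)[1]
    parse_error(path, nums[i],
                paste0("GFF3 line has ", nf[i], " column(s); 9 required"))
  }
  score_raw <- nth_field(parts, 6)
  phase_raw <- nth_field(parts, 8)
  tibble(
    chrom = nth_field(parts, 1),
    source = nth_field(parts, 2),
    type = nth_field(parts, 3),
    start = num_field(nth_field(parts, 4), nums, path, "start"),
    end = num_field(nth_field(parts, 5), nums, path, "end"),
    score = suppressWarnings(as.numeric(ifelse(score_raw == ".", NA, score_raw))),
    strand = nth_field(parts, 7),
    phase = ifelse(phase_raw == ".", NA_character_, phase_raw),
    attributes = nth_field(parts, 9))
}

VCF_EMPTY <- function() {
  tibble(chrom = character(), start = numeric(), end = numeric(),
         id = character(), ref = character(), alt = character(),
         qual = numeric(), filter = character(), info = character())
}

parse_vcf_rows <- function(lines, nums, path) {
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 8)) {
    i <- which(nf < 8)[1]
    parse_error(path, nums[i],
                paste0("VCF record has ", nf[i], " column(s); 8 required"))
  }
  pos <- num_field(nth_field(parts, 2), nums, path, "POS")
  ref <- nth_field(parts, 4)
  qual_raw <- nth_field(parts, 6)
  tibble(
    chrom = nth_field(parts, 1),
    start = pos,
    end = pos + nchar(ref) - 1,  # REF span; INFO END is not interpreted
    id = nth_field(parts, 3),
    ref = ref,
    alt = nth_field(parts, 5),
    qual = suppressWarnings(as.numeric(ifelse(qual_raw == ".", NA, qual_raw))),
    filter = nth_field(parts, 7),
    info = nth_field(parts, 8))
}

# ---------------------------------------------------------------------------
# Batch scanner
# ---------------------------------------------------------------------------

#' Scan an interval file as a stream of batches
#'
#' Opens a BED/GFF3/VCF/TSV file and returns a batch iterator (the shape
#' [iv_stream()] consumes): each call yields up to `batch_size` parsed
#' data rows, skipping comment and header lines per format; at most one
#' batch of parsed rows is held at a time. Concatenating the batches
#' equals the eager read of the same file. A malformed line raises an
#' error naming the file and line number when the batch containing it is
#' parsed; batches before it are yielded normally.
#'
#' @param path File path (plain or gzip text).
#' @param format `"bed"`, `"gff3"`, `"vcf"`, `"tsv"`; default detected
#'   from the extension.
#' @param batch_size Maximum data rows per batch.
#' @return An iterator function; see [iv_batches()] for the batch shape.
#' @export
iv_scan <- function(path, format = NULL, batch_size = 65536) {
  stopifnot(batch_size >= 1)
  format <- format %||% detect_format(path)
  format <- match.arg(format, c("bed", "gff3", "vcf", "tsv"))
  con <- open_text(path)
  e <- new.env(parent = emptyenv())
  e$line_no <- 0L
  e$buf <- character(0)
  e$nums <- integer(0)
  e$eof <- FALSE
  e$done <- FALSE
  e$open <- TRUE
  e$header_seen <- FALSE   # VCF #CHROM line
  e$halted <- FALSE        # GFF3 ##FASTA trailer
  e$col_names <- NULL      # TSV header
  e$batch_i <- 0L
  # close the connection if the iterator is abandoned before EOF
  reg.finalizer(e, function(env) {
    if (isTRUE(env$open)) try(close(con), silent = TRUE)
  })
  read_chunk_lines <- max(1024L, as.integer(min(batch_size, 1e6)))

  fill <- function() {
    while (!e$eof && length(e$buf) <= batch_size) {
      lines <- readLines(con, n = read_chunk_lines)
      if (length(lines) == 0) {
        e$eof <- TRUE
        close(con)
        e$open <- FALSE
        break
      }
      nums <- e$line_no + seq_along(lines)
      e$line_no <- e$line_no + length(lines)
      lines <- sub("\r$", "", lines)
      if (e$halted) next
      if (format == "gff3") {
        halt_at <- which(startsWith(lines, "##FASTA"))[1]
        if (!is.na(halt_at)) {
          lines <- lines[seq_len(halt_at - 1)]
          nums <- nums[seq_len(halt_at - 1)]
          e$halted <- TRUE
        }
      }
      keep <- switch(format,
        bed = !(grepl("^(track|browser|#)", lines) | lines == ""),
        gff3 = !(startsWith(lines, "#") | lines == ""),
        vcf = vcf_keep(e, lines, nums, path),
        tsv = tsv_keep(e, lines))
      e$buf <- c(e$buf, lines[keep])
      e$nums <- c(e$nums, nums[keep])
    }
  }

  function() {
    if (e$done) return(NULL)
    fill()
    if (length(e$buf) == 0 && e$eof) {
      e$done <- TRUE
      if (format == "vcf" && !e$header_seen) {
        abort(paste0(path, ": missing #CHROM header line"),
              class = "rangekit_parse_error")
      }
      return(NULL)
    }
    take <- min(batch_size, length(e$buf))
    lines <- e$buf[seq_len(take)]
    nums <- e$nums[seq_len(take)]
    e$buf <- e$buf[-seq_len(take)]
    e$nums <- e$nums[-seq_len(take)]
    dat <- switch(format,
      bed = parse_bed_rows(lines, nums, path),
      gff3 = parse_gff3_rows(lines, nums, path),
      vcf = parse_vcf_rows(lines, nums, path),
      tsv = parse_tsv_rows(e, lines, nums, path))
    e$batch_i <- e$batch_i + 1L
    is_last <- e$eof && length(e$buf) == 0
    if (is_last) {
      e$done <- TRUE
      if (format == "vcf" && !e$header_seen) {
        abort(paste0(path, ": missing #CHROM header line"),
              class = "rangekit_parse_error")
      }
    }
    list(data = set_coords(dat, fmt_coords(format)),
         batch_index = e$batch_i, is_last = is_last)
  }
}

vcf_keep <- function(e, lines, nums, path) {
  meta <- startsWith(lines, "#") | lines == ""
  if (!e$header_seen) {
    hdr_at <- which(startsWith(lines, "#CHROM"))[1]
    data_at <- which(!meta)[1]
    if (!is.na(data_at) && (is.na(hdr_at) || data_at < hdr_at)) {
      parse_error(path, nums[data_at],
                  "data record before #CHROM header line")
    }
    if (!is.na(hdr_at)) e$header_seen <- TRUE
  }
  !meta
}

tsv_keep <- function(e, lines) {
  keep <- lines != ""
  if (is.null(e$col_names)) {
    first <- which(keep)[1]
    if (!is.na(first)) {
      e$col_names <- strsplit(lines[first], "\t", fixed = TRUE)[[1]]
      keep[first] <- FALSE
    }
  }
  keep
}

parse_tsv_rows <- function(e, lines, nums, path) {
  cols <- e$col_names
  if (is.null(cols) || !all(IV_COLS %in% cols)) {
    abort(paste0(path, ": TSV header must include chrom, start, end"),
          class = "rangekit_parse_error")
  }
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  short <- which(nf > length(cols))
  if (length(short) > 0) {
    parse_error(path, nums[short[1]],
                paste0("row has ", nf[short[1]], " fields; header has ",
                       length(cols)))
  }
  out <- tibble(.rows = length(lines))
  for (j in seq_along(cols)) {
    v <- nth_field(parts, j)
    v[!is.na(v) & v == ""] <- NA_character_
    if (cols[j] %in% c("start", "end")) {
      v <- num_field(v, nums, path, cols[j])
    }
    out[[cols[j]]] <- v
  }
  out
}

collect_scan <- function(it, empty) {
  chunks <- list()
  repeat {
    batch <- it()
    if (is.null(batch)) break
    chunks[[length(chunks) + 1L]] <- batch$data
  }
  if (length(chunks) == 0) return(empty)
  out <- bind_rows(chunks)
  set_coords(out, iv_coords(chunks[[1]]))
}

#' Read a BED file
#'
#' BED3 and wider: `chrom`, `chromStart`, `chromEnd`, then the optional
#' `name`, `score`, `strand` columns (score as integer where clean) and
#' any further columns preserved as opaque strings (`col7`, `col8`, ...).
#' `track`, `browser` and `#` lines are skipped. The result is tagged
#' 0-based half-open and keeps the file's row order.
#'
#' @inheritParams iv_scan
#' @return An interval frame (see [iv_frame()]).
#' @export
read_bed <- function(path) {
  out <- collect_scan(iv_scan(path, "bed", batch_size = 1048576),
                      tibble(chrom = character(), start = numeric(),
                             end = numeric()))
  set_coords(out, "zero_based_half_open")
}

#' Read a GFF3 file
#'
#' Nine-column GFF3; `#` comment and `##` directive lines are skipped and
#' a `##FASTA` trailer halts parsing. Columns: `chrom`, `source`, `type`,
#' `start`, `end`, `score` (`.` becomes `NA`), `strand`, `phase` (`.`
#' becomes `NA`), `attributes` (the raw column-9 string — attributes are
#' deliberately not unpacked). Tagged 1-based closed.
#'
#' @inheritParams iv_scan
#' @return An interval frame.
#' @export
read_gff3 <- function(path) {
  out <- collect_scan(iv_scan(path, "gff3", batch_size = 1048576),
                      GFF3_EMPTY())
  set_coords(out, "one_based_closed")
}

#' Read a VCF file
#'
#' VCF 4.x text: `##` meta lines and the mandatory `#CHROM` header are
#' consumed; sample columns are ignored. Each record becomes the interval
#' spanned by its REF allele: `start = POS`, `end = POS + nchar(REF) - 1`
#' (so an SNV is a single base and a 4-base REF spans 4). `INFO END` and
#' symbolic ALT spans are deliberately not interpreted. Columns: `chrom`,
#' `start`, `end`, `id`, `ref`, `alt` (raw comma-joined), `qual` (`.`
#' becomes `NA`), `filter`, `info` (raw string). Tagged 1-based closed.
#'
#' @inheritParams iv_scan
#' @return An interval frame.
#' @export
read_vcf <- function(path) {
  out <- collect_scan(iv_scan(path, "vcf", batch_size = 1048576), VCF_EMPTY())
  set_coords(out, "one_based_closed")
}

#' Write a result table as TSV or CSV
#'
#' Writes a header row of column names; `NA` values become empty fields.
#' Reading the file back (empty fields as `NA`) reproduces the values.
#' `path = "-"` writes to standard output.
#'
#' @param x A data frame (typically a join result).
#' @param path Output path, or `"-"` for standard output.
#' @param format `"tsv"` or `"csv"`.
#' @param append,col_names Append to an existing file without repeating
#'   the header (used by the streaming sink).
#' @return `x`, invisibly.
#' @export
write_table <- function(x, path, format = c("tsv", "csv"), append = FALSE,
                        col_names = !append) {
  format <- match.arg(format)
  x <- as_tibble(x)
  txt <- if (format == "tsv") {
    readr::format_tsv(x, na = "", col_names = col_names)
  } else {
    readr::format_csv(x, na = "", col_names = col_names)
  }
  if (identical(path, "-")) {
    cat(txt)
  } else {
    cat(txt, file = path, append = append)
  }
  invisible(x)
}

#' Write an interval frame as BED
#'
#' Converts to 0-based half-open coordinates and writes `chrom`, `start`,
#' `end` plus any payload columns, tab-separated without a header (`NA`
#' payload as `.`).
#'
#' @inheritParams iv_validate
#' @param path Output path.
#' @return `x`, invisibly.
#' @export
write_bed <- function(x, path, coords = NULL) {
  check_iv_columns(x)
  caller <- resolve_coords(x, coords)
  h <- iv_convert(set_coords(as_tibble(x), caller), "zero_based_half_open")
  h <- h[c(IV_COLS, setdiff(names(h), IV_COLS))]
  cols <- lapply(h, function(col) {
    out <- if (is.numeric(col)) format(col, scientific = FALSE, trim = TRUE)
           else as.character(col)
    out[is.na(col)] <- "."
    out
  })
  writeLines(do.call(paste, c(cols, sep = "\t")), path)
  invisible(x)
}
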