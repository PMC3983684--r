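#' @importFrom data.table fread fwrite
NULL

#' Read a multi-class transcript annotation
#'
#' Supported dialects: GTF 2.2 (`transcript` feature lines carrying
#' `transcript_id` and `rna_class` attributes; 1-based inclusive coordinates
#' are converted to the internal 0-based half-open convention) and BED12
#' with a 13th column holding the RNA class.
#'
#' @param path file path.
#' @param format `"GTF"` or `"BED12"`.
#' @return transcript table (see [transcript_table()]).
#' @export
read_annotation <- function(path, format = c("GTF", "BED12")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("annotation file not found: ", path)
  lines <- readLines(path)
  keep <- !startsWith(lines, "#") & nzchar(lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (format == "GTF") {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf != 9))
      stop("malformed GTF line ", lineno[which(nf != 9)[1]],
           ": expected 9 tab-separated fields")
    m <- do.call(rbind, fields)
    feat <- m[, 3] == "transcript"
    if (!any(feat)) stop("no 'transcript' feature lines in GTF")
    m <- m[feat, , drop = FALSE]
    ln <- lineno[feat]
    attr_field <- m[, 9]
    get_attr <- function(key) {
      re <- paste0(key, ' "([^"]*)"')
      mm <- regmatches(attr_field, regexec(re, attr_field))
      vapply(mm, function(x) if (length(x) == 2) x[2] else NA_character_, "")
    }
    id <- get_attr("transcript_id")
    cls <- get_attr("rna_class")
    if (anyNA(id))
      stop("malformed GTF line ", ln[which(is.na(id))[1]],
           ": missing transcript_id attribute")
    if (anyNA(cls))
      stop("malformed GTF line ", ln[which(is.na(cls))[1]],
           ": missing rna_class attribute")
    start1 <- suppressWarnings(as.integer(m[, 4]))
    end1 <- suppressWarnings(as.integer(m[, 5]))
    if (anyNA(start1) || anyNA(end1))
      stop("malformed GTF line ",
           ln[which(is.na(start1) | is.na(end1))[1]],
           ": non-numeric coordinates")
    transcript_table(id = id, chrom = m[, 1], start = start1 - 1L,
                     end = end1, strand = m[, 7], rna_class = cls)
  } else {
    fields <- strsplit(lines, "\t", fixed = TRUE)
    nf <- lengths(fields)
    if (any(nf < 13))
      stop("malformed BED12 line ", lineno[which(nf < 13)[1]],
           ": expected 12 columns plus an RNA-class column")
    m <- do.call(rbind, lapply(fields, `[`, 1:13))
    transcript_table(id = m[, 4], chrom = m[, 1],
                     start = as.integer(m[, 2]), end = as.integer(m[, 3]),
                     strand = m[, 6], rna_class = m[, 13])
  }
}

#' Write a transcript annotation as GTF
#'
#' Inverse of [read_annotation()] for the GTF dialect: internal 0-based
#' half-open coordinates are printed 1-based inclusive.
#'
#' @param tx transcript table.
#' @param path output path.
#' @export
write_annotation <- function(tx, path) {
  attrs <- sprintf('transcript_id "%s"; rna_class "%s";', tx$id, tx$rna_class)
  lines <- sprintf("%s\thypoxtx\ttranscript\t%d\t%d\t.\t%s\t.\t%s",
                   tx$chrom, tx$start + 1L, tx$end, tx$strand, attrs)
  writeLines(lines, path)
  invisible(path)
}

#' Read a ChIP peak set from BED
#'
#' BED3 or more; an optional 5th numeric column is interpreted as the summit
#' offset from `start` (narrowPeak-style); otherwise the summit defaults to
#' the interval midpoint. Peaks are unstranded.
#'
#' @param path BED file.
#' @param factor `"HIF1"` or `"HIF2"`.
#' @param summit_col index of the summit-offset column, or `NA` to use the
#'   midpoint (columns beyond 4 are ignored unless named here).
#' @return data.frame with `id`, `chrom`, `start`, `end`, `strand` (`.`),
#'   `summit`, `factor`.
#' @export
read_peaks <- function(path, factor = c("HIF1", "HIF2"), summit_col = 5L) {
  factor <- match.arg(factor)
  if (!file.exists(path)) stop("peak file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  if (length(lines) == 0) {
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), summit = integer(),
                      factor = character(), stringsAsFactors = FALSE))
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3)) stop("BED peak file needs >= 3 columns")
  chrom <- vapply(fields, `[`, "", 1)
  start <- as.integer(vapply(fields, `[`, "", 2))
  end <- as.integer(vapply(fields, `[`, "", 3))
  if (any(is.na(start) | is.na(end))) stop("non-numeric BED coordinates")
  if (any(end <= start)) stop("peak end must be > start")
  id <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    if (length(f) >= 4 && nzchar(f[4]) && f[4] != ".") f[4]
    else paste0(factor, "_peak_", i)
  }, "")
  off <- vapply(fields, function(f) {
    if (!is.na(summit_col) && length(f) >= summit_col) {
      v <- suppressWarnings(as.integer(f[summit_col]))
      if (!is.na(v) && v >= 0) v else NA_integer_
    } else NA_integer_
  }, 1L)
  summit <- ifelse(is.na(off), start + (end - start) %/% 2L, start + off)
  if (any(summit < start | summit >= end))
    stop("peak summit outside interval")
  data.frame(id = id, chrom = chrom, start = start, end = end,
             strand = ".", summit = as.integer(summit), factor = factor,
             stringsAsFactors = FALSE)
}

#' Read chromosome sizes
#'
#' Two-column, headerless TSV: chromosome name and length in bp.
#'
#' @param path file path.
#' @return named integer vector of lengths.
#' @export
read_chrom_sizes <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "length"),
                          colClasses = c("character", "integer"))
  if (any(df$length <= 0)) stop("chromosome lengths must be positive")
  setNames(df$length, df$chrom)
}

#' @rdname read_chrom_sizes
#' @param sizes named integer vector.
#' @export
write_chrom_sizes <- function(sizes, path) {
  writeLines(sprintf("%s\t%d", names(sizes), as.integer(sizes)), path)
  invisible(path)
}

#' Construct a coverage track
#'
#' A coverage track holds one non-negative per-base signal vector per
#' chromosome, plus the mark and condition it measures.
#'
#' @param values named list of numeric vectors (one per chromosome;
#'   element `i` is the signal at 0-based position `i - 1`).
#' @param mark one of `"RNApol2"`, `"H3K4me3"`, `"DNase"`, `"RNAseq"`.
#' @param condition free-text condition label (e.g. `"normoxia"`).
#' @param strand `"+"`, `"-"` or `"."` (stranded RNA-seq coverage only).
#' @return object of class `coverage_track`.
#' @export
coverage_track <- function(values, mark, condition, strand = ".") {
  stopifnot(is.list(values), !is.null(names(values)))
  if (any(vapply(values, function(v) any(v < 0), TRUE)))
    stop("coverage values must be non-negative")
  structure(list(mark = mark, condition = condition, strand = strand,
                 values = values,
                 total_signal = sum(vapply(values, sum, 0))),
            class = "coverage_track")
}

#' @export
print.coverage_track <- function(x, ...) {
  cat(sprintf("<coverage_track> mark=%s condition=%s strand=%s\n",
              x$mark, x$condition, x$strand))
  cat(sprintf("  %d chromosome(s), %d bp, total signal %.4g\n",
              length(x$values), sum(lengths(x$values)), x$total_signal))
  invisible(x)
}

#' Read a bedGraph file into a per-base coverage track
#'
#' Uncovered bases are zero. Overlapping bedGraph records are rejected
#' because the signal there would be ambiguous.
#'
#' @param path bedGraph file (4 columns: chrom, start, end, value).
#' @param mark,condition,strand track labels (see [coverage_track()]).
#' @param chrom_sizes named integer vector from [read_chrom_sizes()].
#' @return a `coverage_track`.
#' @export
read_coverage <- function(path, mark, condition, chrom_sizes, strand = ".") {
  if (!file.exists(path)) stop("bedGraph file not found: ", path)
  df <- data.table::fread(path, sep = "\t", header = FALSE,
                          col.names = c("chrom", "start", "end", "value"),
                          colClasses = list(character = 1),
                          data.table = FALSE)
  if (nrow(df) > 0) {
    if (any(df$value < 0)) stop("negative coverage value in ", path)
    if (any(df$end <= df$start)) stop("bedGraph end must be > start")
    bad <- setdiff(unique(df$chrom), names(chrom_sizes))
    if (length(bad)) stop("bedGraph chromosome not in chrom_sizes: ", bad[1])
    if (any(df$end > chrom_sizes[df$chrom]))
      stop("bedGraph interval beyond chromosome end")
  }
  values <- lapply(names(chrom_sizes), function(cn) {
    v <- numeric(chrom_sizes[[cn]])
    sub <- df[df$chrom == cn, , drop = FALSE]
    if (nrow(sub)) {
      o <- order(sub$start)
      sub <- sub[o, , drop = FALSE]
      if (any(sub$start[-1] < sub$end[-nrow(sub)]))
        stop("overlapping bedGraph intervals on ", cn, " (ambiguous signal)")
      idx <- sequence(nvec = sub$end - sub$start, from = sub$start + 1L)
      v[idx] <- rep(sub$value, sub$end - sub$start)
    }
    v
  })
  names(values) <- names(chrom_sizes)
  coverage_track(values, mark, condition, strand)
}

#' Write a coverage track as bedGraph
#'
#' Zero runs are omitted; adjacent equal values are merged into one record.
#'
#' @param track a `coverage_track`.
#' @param path output path.
#' @export
write_coverage <- function(track, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (cn in names(track$values)) {
    r <- rle(track$values[[cn]])
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths
    nz <- r$values != 0
    if (any(nz)) {
      writeLines(sprintf("%s\t%d\t%d\t%s", cn, starts[nz], ends[nz],
                         sprintf("%.6g", r$values[nz])), con)
    }
  }
  invisible(path)
}

#' Count matrix of transcripts by samples
#'
#' @param counts non-negative integer matrix, rownames = transcript ids,
#'   colnames = sample labels.
#' @return object of class `count_matrix` with fields `counts` and
#'   `lib_sizes` (column sums).
#' @export
count_matrix <- function(counts) {
  counts <- as.matrix(counts)
  if (is.null(colnames(counts)) ||
      (nrow(counts) > 0 && is.null(rownames(counts))))
    stop("count matrix needs transcript rownames and sample colnames")
  if (is.null(rownames(counts))) rownames(counts) <- character(0)
  if (any(counts < 0) || any(counts != round(counts)))
    stop("counts must be non-negative integers")
  storage.mode(counts) <- "double"  # avoids integer overflow in sums
  structure(list(counts = counts, lib_sizes = colSums(counts)),
            class = "count_matrix")
}

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("<count_matrix> %d transcripts x %d samples\n",
              nrow(x$counts), ncol(x$counts)))
  cat("  samples:", paste(colnames(x$counts), collapse = ", "), "\n")
  invisible(x)
}

#' Read / write a count matrix TSV (first column `id`, one column per sample)
#' @param path TSV path.
#' @return a `count_matrix`.
#' @export
read_counts <- function(path) {
  df <- data.table::fread(path, sep = "\t", header = TRUE,
                          data.table = FALSE)
  m <- as.matrix(df[, -1, drop = FALSE])
  rownames(m) <- df[[1]]
  count_matrix(m)
}

#' @rdname read_counts
#' @param cm a `count_matrix`.
#' @export
write_counts <- function(cm, path) {
  df <- data.frame(id = rownames(cm$counts), cm$counts,
                   check.names = FALSE, stringsAsFactors = FALSE)
  write_table(df, path)
}

#' Write a data frame as a deterministic TSV
#'
#' Tab-separated with a header line; rows are sorted by the first column so
#' repeated runs produce byte-identical files.
#'
#' @param rows data.frame.
#' @param path output path.
#' @param columns optional schema: required column names, in order.
#' @export
write_table <- function(rows, path, columns = NULL) {
  if (!is.null(columns)) {
    missing <- setdiff(columns, names(rows))
    if (length(missing))
      stop("rows do not conform to schema; missing column(s): ",
           paste(missing, collapse = ", "))
    rows <- rows[, columns, drop = FALSE]
  }
  if (nrow(rows) > 1) rows <- rows[order(rows[[1]]), , drop = FALSE]
  data.table::fwrite(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' @rdname write_table
#' @export
read_table <- function(path) {
  data.table::fread(path, sep = "\t", header = TRUE, data.table = FALSE)
}

#' Write peaks as BED (with a summit-offset column 5)
#' @param peaks peak data.frame from [read_peaks()].
#' @param path output path.
#' @export
write_peaks <- function(peaks, path) {
  peaks <- peaks[order(peaks$id), , drop = FALSE]
  writeLines(sprintf("%s\t%d\t%d\t%s\t%d", peaks$chrom, peaks$start,
                     peaks$end, peaks$id, peaks$summit - peaks$start), path)
  invisible(path)
}
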