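#' @importFrom GenomicRanges GRanges findOverlaps
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors queryHits subjectHits
#' @importFrom stats median quantile rnbinom rpois runif rnorm cor setNames
#'   pnorm ave
#' @importFrom graphics hist
#' @importFrom utils head tail
NULL

# Closed vocabulary of RNA classes handled by the class-assignment cascade.
RNA_CLASSES <- c("mRNA", "lncRNA", "miRNA", "snRNA", "tRNA", "piwiRNA",
                 "rRNA", "novel")

STRANDS <- c("+", "-", ".")

#' Construct a validated table of genomic intervals
#'
#' Intervals use the BED convention throughout the package: 0-based,
#' half-open `[start, end)`. Strand `"."` (unstranded) is permitted only
#' where the caller allows it (peaks and coverage); transcripts must be
#' stranded because the analyses assume directional libraries.
#'
#' @param chrom character vector of chromosome names.
#' @param start,end integer vectors; `0 <= start < end`.
#' @param strand character vector in `c("+", "-", ".")`.
#' @param allow_unstranded logical; if `FALSE`, strand `"."` is rejected.
#' @return a `data.frame` with columns `chrom`, `start`, `end`, `strand`.
#' @export
genomic_intervals <- function(chrom, start, end, strand = ".",
                              allow_unstranded = TRUE) {
  n <- max(length(chrom), length(start), length(end), length(strand))
  chrom <- rep_len(as.character(chrom), n)
  start <- rep_len(as.integer(start), n)
  end <- rep_len(as.integer(end), n)
  strand <- rep_len(as.character(strand), n)
  if (any(is.na(start)) || any(is.na(end)))
    stop("interval coordinates must be integers")
  if (any(start < 0))
    stop("interval start must be >= 0")
  if (any(end <= start))
    stop("interval end must be > start (half-open convention)")
  if (!all(strand %in% STRANDS))
    stop("strand must be one of '+', '-', '.'")
  if (!allow_unstranded && any(strand == "."))
    stop("unstranded intervals not allowed here")
  data.frame(chrom = chrom, start = start, end = end,
             strand = strand, stringsAsFactors = FALSE)
}

#' Construct a transcript annotation table
#'
#' A transcript is a stranded interval with a class label. The TSS is the
#' 5' end: `start` on the `+` strand and `end - 1` on the `-` strand.
#'
#' @param id unique transcript identifiers.
#' @param chrom,start,end,strand interval fields (see [genomic_intervals()]).
#' @param rna_class one of `r paste(RNA_CLASSES, collapse = ", ")`.
#' @return data.frame with columns `id`, `chrom`, `start`, `end`, `strand`,
#'   `rna_class`, `tss`, `length`, sorted as given.
#' @export
transcript_table <- function(id, chrom, start, end, strand, rna_class) {
  iv <- genomic_intervals(chrom, start, end, strand, allow_unstranded = FALSE)
  id <- as.character(id)
  if (anyDuplicated(id))
    stop("duplicate transcript id(s): ",
         paste(unique(id[duplicated(id)]), collapse = ", "))
  rna_class <- as.character(rna_class)
  bad <- setdiff(unique(rna_class), RNA_CLASSES)
  if (length(bad))
    stop("unknown RNA class label(s): ", paste(bad, collapse = ", "))
  tx <- cbind(data.frame(id = id, stringsAsFactors = FALSE), iv)
  tx$rna_class <- rna_class
  tx$tss <- ifelse(tx$strand == "+", tx$start, tx$end - 1L)
  tx$length <- tx$end - tx$start
  tx
}

# GRanges view of an interval table (1-based closed, as IRanges expects).
.as_granges <- function(df) {
  GenomicRanges::GRanges(
    seqnames = df$chrom,
    ranges = IRanges::IRanges(start = df$start + 1L, end = df$end),
    strand = ifelse(df$strand == ".", "*", df$strand))
}

#' Test whether two intervals overlap
#'
#' Half-open overlap on the same chromosome, with a strand relation:
#' `any_strand` ignores strand, `same_strand` requires equal strands and
#' `opposite_strand` requires one `+` and one `-`. Unstranded (`"."`)
#' intervals satisfy neither `same_strand` nor `opposite_strand`.
#'
#' @param a,b single-row interval data.frames (or lists) with fields
#'   `chrom`, `start`, `end`, `strand`.
#' @param mode one of `"any_strand"`, `"same_strand"`, `"opposite_strand"`.
#' @return logical scalar.
#' @export
overlaps <- function(a, b, mode = c("any_strand", "same_strand",
                                    "opposite_strand")) {
  mode <- match.arg(mode)
  if (a$chrom != b$chrom) return(FALSE)
  if (a$start >= b$end || b$start >= a$end) return(FALSE)
  switch(mode,
    any_strand = TRUE,
    same_strand = a$strand != "." && a$strand == b$strand,
    opposite_strand = (a$strand == "+" && b$strand == "-") ||
                      (a$strand == "-" && b$strand == "+"))
}

#' All overlapping pairs between two interval tables
#'
#' Indexed overlap query used by the class-assignment cascade and the novel
#' transcript classifier. Results are identical to a brute-force all-pairs
#' scan with [overlaps()].
#'
#' @param query,subject interval data.frames (any extra columns kept aside).
#' @param mode strand relation as in [overlaps()].
#' @return data.frame with `query_idx`, `subject_idx`, `overlap_width`
#'   (bp of intersection).
#' @export
overlap_hits <- function(query, subject,
                         mode = c("any_strand", "same_strand",
                                  "opposite_strand")) {
  mode <- match.arg(mode)
  empty <- data.frame(query_idx = integer(), subject_idx = integer(),
                      overlap_width = integer())
  if (nrow(query) == 0 || nrow(subject) == 0) return(empty)
  gq <- .as_granges(query)
  gs <- .as_granges(subject)
  if (mode == "opposite_strand") {
    inv <- c("+" = "-", "-" = "+", "." = ".")
    gq <- .as_granges(transform(query, strand = unname(inv[strand])))
  }
  ignore <- mode == "any_strand"
  hits <- GenomicRanges::findOverlaps(gq, gs, ignore.strand = ignore)
  qi <- S4Vectors::queryHits(hits)
  si <- S4Vectors::subjectHits(hits)
  if (mode != "any_strand") {
    # '.' maps to GRanges '*' which matches everything; exclude it here so
    # unstranded intervals never satisfy a stranded mode
    ok <- query$strand[qi] != "." & subject$strand[si] != "."
    qi <- qi[ok]; si <- si[ok]
  }
  ow <- pmin(query$end[qi], subject$end[si]) -
        pmax(query$start[qi], subject$start[si])
  data.frame(query_idx = qi, subject_idx = si, overlap_width = ow)
}
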