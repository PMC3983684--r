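#' Default class priority for the sequential assignment cascade
#'
#' Features are assigned to the highest-priority RNA class with a
#' same-strand overlapping transcript, mirroring sequential mapping against
#' per-class databases: short/structural RNA databases are consulted before
#' long-RNA annotation so that, e.g., a miRNA hosted in an mRNA intron is
#' counted as a miRNA. The order is a convention, not a measurement, and is
#' recorded in pipeline provenance.
#'
#' @return character vector of class labels, highest priority first.
#' @export
default_class_priority <- function() {
  c("rRNA", "tRNA", "snRNA", "miRNA", "piwiRNA", "mRNA", "lncRNA")
}

.check_priority <- function(priority, annotation) {
  if (anyDuplicated(priority)) stop("class priority contains duplicates")
  missing <- setdiff(unique(annotation$rna_class), priority)
  missing <- setdiff(missing, "novel")
  if (length(missing))
    stop("class priority does not cover annotated class(es): ",
         paste(missing, collapse = ", "))
}

#' Assign one feature to an RNA class
#'
#' The highest-priority class with a same-strand overlapping transcript
#' wins; within a class, ties are broken by largest overlap length, then by
#' lexicographically smallest transcript id. Features overlapping nothing on
#' the same strand are unassigned (`NA`): the libraries are directional, so
#' opposite-strand annotation does not explain a feature.
#'
#' @param feature single-row stranded interval data.frame.
#' @param annotation transcript table.
#' @param priority character vector of classes, highest first.
#' @return list with `rna_class` and `transcript_id` (both `NA` if
#'   unassigned).
#' @export
assign_class <- function(feature, annotation,
                         priority = default_class_priority()) {
  res <- classify_features(feature, annotation, priority)
  list(rna_class = res$rna_class[1], transcript_id = res$transcript_id[1])
}

#' Vectorised class assignment
#'
#' @param features stranded interval data.frame (one row per feature).
#' @inheritParams assign_class
#' @return data.frame with one row per feature: `rna_class`,
#'   `transcript_id`, `overlap_width` (`NA` where unassigned).
#' @export
classify_features <- function(features, annotation,
                              priority = default_class_priority()) {
  .check_priority(priority, annotation)
  n <- nrow(features)
  out <- data.frame(rna_class = rep(NA_character_, n),
                    transcript_id = rep(NA_character_, n),
                    overlap_width = rep(NA_integer_, n),
                    stringsAsFactors = FALSE)
  hits <- overlap_hits(features, annotation, mode = "same_strand")
  if (!nrow(hits)) return(out)
  hits$rna_class <- annotation$rna_class[hits$subject_idx]
  hits$transcript_id <- annotation$id[hits$subject_idx]
  hits$prio <- match(hits$rna_class, priority)
  hits <- hits[!is.na(hits$prio), , drop = FALSE]
  if (!nrow(hits)) return(out)
  # best hit per feature: smallest priority rank, largest overlap, then id
  o <- order(hits$query_idx, hits$prio, -hits$overlap_width,
             hits$transcript_id)
  hits <- hits[o, , drop = FALSE]
  best <- hits[!duplicated(hits$query_idx), , drop = FALSE]
  out$rna_class[best$query_idx] <- best$rna_class
  out$transcript_id[best$query_idx] <- best$transcript_id
  out$overlap_width[best$query_idx] <- best$overlap_width
  out
}

#' Classify all features and partition them
#'
#' Applies [classify_features()] and splits the input into assigned
#' features (per class), unassigned features (candidate input for novel
#' transcript discovery) and features diverted as ribosomal. The partition
#' is exact: `assigned + unassigned + rRNA_removed` equals the input count.
#'
#' @inheritParams classify_features
#' @return list with `assignments` (features plus assignment columns),
#'   `per_class` (named count vector), `unassigned` (feature subset),
#'   `rRNA_removed` (count).
#' @export
classify_all <- function(features, annotation,
                         priority = default_class_priority()) {
  cls <- classify_features(features, annotation, priority)
  assignments <- cbind(features, cls)
  is_rrna <- !is.na(cls$rna_class) & cls$rna_class == "rRNA"
  unassigned <- features[is.na(cls$rna_class), , drop = FALSE]
  kept <- !is.na(cls$rna_class) & !is_rrna
  per_class <- table(factor(cls$rna_class[kept],
                            levels = setdiff(priority, "rRNA")))
  list(assignments = assignments,
       per_class = setNames(as.integer(per_class), names(per_class)),
       unassigned = unassigned,
       rRNA_removed = sum(is_rrna))
}

#' Default class-specific abundance thresholds
#'
#' Classes of longer RNAs get a higher threshold, since their counts
#' accumulate over more positions: minimum mean raw count 10 for classes
#' whose median annotated length is under 200 nt, 50 otherwise.
#'
#' @param annotation transcript table (used for median class lengths).
#' @return named numeric vector of per-class thresholds.
#' @export
default_thresholds <- function(annotation) {
  med <- tapply(annotation$length, annotation$rna_class, median)
  setNames(ifelse(med < 200, 10, 50), names(med))
}

#' Filter low-abundance transcripts
#'
#' A transcript survives iff its mean raw count across the two contrast
#' samples is at least its class threshold (boundary inclusive). Row order
#' is preserved.
#'
#' @param counts a [count_matrix()].
#' @param classes named character vector: class per transcript id.
#' @param thresholds named numeric vector of per-class minimum mean counts;
#'   must cover every class present.
#' @param contrast length-2 character: the two sample columns whose mean is
#'   thresholded.
#' @return filtered `count_matrix`.
#' @export
filter_low_abundance <- function(counts, classes, thresholds,
                                 contrast = c("normoxia", "hypoxia")) {
  m <- counts$counts
  if (!all(contrast %in% colnames(m)))
    stop("contrast sample(s) not in count matrix: ",
         paste(setdiff(contrast, colnames(m)), collapse = ", "))
  cls <- classes[rownames(m)]
  if (anyNA(cls)) stop("class labels missing for some transcripts")
  missing <- setdiff(unique(cls), names(thresholds))
  if (length(missing))
    stop("no abundance threshold for class(es): ",
         paste(missing, collapse = ", "))
  keep <- rowMeans(m[, contrast, drop = FALSE]) >= thresholds[cls]
  count_matrix(m[keep, , drop = FALSE])
}
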