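#' Assemble candidate transcripts from unexplained stranded coverage
#'
#' Single-exon coverage-merge assembly: bases with signal of at least
#' `min_depth` that are not covered by same-strand annotation are merged
#' into candidate loci when separated by gaps of at most `max_gap` bp;
#' candidates shorter than `min_length` are dropped. The putative TSS of a
#' candidate is its 5'-most covered base.
#'
#' @param coverage named list of [coverage_track()]s for strands `"+"` and
#'   `"-"` (stranded RNA-seq coverage).
#' @param annotation transcript table of known (public) transcripts.
#' @param min_depth minimum per-base signal (default 1).
#' @param max_gap maximum merged gap (default 100 bp).
#' @param min_length minimum candidate length (default 200 bp).
#' @return stranded interval data.frame: `id`, `chrom`, `start`, `end`,
#'   `strand`, `tss`, `length`.
#' @export
assemble_unexplained <- function(coverage, annotation, min_depth = 1,
                                 max_gap = 100L, min_length = 200L) {
  out <- list()
  for (st in c("+", "-")) {
    track <- coverage[[st]]
    if (is.null(track)) next
    for (cn in names(track$values)) {
      v <- track$values[[cn]]
      covered <- v >= min_depth
      ann <- annotation[annotation$chrom == cn &
                        annotation$strand == st, , drop = FALSE]
      if (nrow(ann)) {
        mask <- logical(length(v))
        idx <- sequence(nvec = ann$end - ann$start, from = ann$start + 1L)
        mask[idx[idx <= length(v)]] <- TRUE
        covered <- covered & !mask
      }
      r <- rle(covered)
      ends <- cumsum(r$lengths)
      starts <- ends - r$lengths        # 0-based starts
      ok <- r$values
      if (!any(ok)) next
      bs <- starts[ok]; be <- ends[ok]
      # merge blocks separated by small gaps
      if (length(bs) > 1) {
        gap <- bs[-1] - be[-length(be)]
        new_block <- c(TRUE, gap > max_gap)
        grp <- cumsum(new_block)
        bs <- tapply(bs, grp, min)
        be <- tapply(be, grp, max)
      }
      keep <- (be - bs) >= min_length
      if (!any(keep)) next
      out[[length(out) + 1]] <-
        data.frame(chrom = cn, start = as.integer(bs[keep]),
                   end = as.integer(be[keep]), strand = st,
                   stringsAsFactors = FALSE)
    }
  }
  if (!length(out))
    return(data.frame(id = character(), chrom = character(),
                      start = integer(), end = integer(),
                      strand = character(), tss = integer(),
                      length = integer()))
  cand <- do.call(rbind, out)
  cand <- cand[order(cand$chrom, cand$start, cand$strand), , drop = FALSE]
  cand$id <- sprintf("cand_%04d", seq_len(nrow(cand)))
  cand$tss <- ifelse(cand$strand == "+", cand$start, cand$end - 1L)
  cand$length <- cand$end - cand$start
  rownames(cand) <- NULL
  cand[, c("id", "chrom", "start", "end", "strand", "tss", "length")]
}

#' Classify assembled candidates as intergenic or antisense
#'
#' A candidate overlapping nothing on either strand is intergenic; one
#' whose only overlaps are on the opposite strand is antisense (linked to
#' the largest-overlap sense transcript); any same-strand overlap means the
#' candidate is explained by existing annotation and is discarded.
#'
#' @param candidates stranded interval data.frame (from
#'   [assemble_unexplained()]).
#' @param annotation transcript table of known transcripts.
#' @return data.frame of retained candidates with `category`
#'   (`"intergenic"`/`"antisense"`) and `overlapping_sense_id` (`NA` for
#'   intergenic).
#' @export
classify_novel <- function(candidates, annotation) {
  if (!nrow(candidates)) {
    candidates$category <- character()
    candidates$overlapping_sense_id <- character()
    return(candidates)
  }
  same <- overlap_hits(candidates, annotation, mode = "same_strand")
  anti <- overlap_hits(candidates, annotation, mode = "opposite_strand")
  has_same <- seq_len(nrow(candidates)) %in% same$query_idx
  has_anti <- seq_len(nrow(candidates)) %in% anti$query_idx
  partner <- rep(NA_character_, nrow(candidates))
  if (nrow(anti)) {
    anti$sense_id <- annotation$id[anti$subject_idx]
    o <- order(anti$query_idx, -anti$overlap_width, anti$sense_id)
    anti <- anti[o, , drop = FALSE]
    best <- anti[!duplicated(anti$query_idx), ]
    partner[best$query_idx] <- best$sense_id
  }
  out <- candidates
  out$category <- ifelse(has_anti, "antisense", "intergenic")
  out$overlapping_sense_id <- partner
  out <- out[!has_same, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Find CpG islands by sliding-window composition
#'
#' Gardiner-Garden-Frommer style criteria: windows of `window` bp
#' (advanced by `step`) qualify when G+C fraction >= `gc_min` and the
#' observed/expected CpG ratio `(CpG count x length) / (C count x G count)`
#' is >= `oe_min`. Qualifying windows are merged into maximal segments,
#' each merged segment is re-tested as a whole, and segments shorter than
#' `min_length` are dropped.
#'
#' @param sequence named character vector of chromosome sequences
#'   (A/C/G/T/N).
#' @param min_length,gc_min,oe_min,window,step criteria (defaults 200 bp,
#'   0.5, 0.6, 200, 1).
#' @return data.frame: `chrom`, `start`, `end` (0-based half-open),
#'   `length`, `gc_fraction`, `obs_exp_cpg`.
#' @export
find_cpg_islands <- function(sequence, min_length = 200L, gc_min = 0.5,
                             oe_min = 0.6, window = 200L, step = 1L) {
  res <- list()
  for (cn in names(sequence)) {
    s <- strsplit(sequence[[cn]], "", fixed = TRUE)[[1]]
    L <- length(s)
    if (L < window) next
    is_c <- s == "C"
    is_g <- s == "G"
    is_cg <- c(is_c[-L] & is_g[-1], FALSE)
    cum_c <- c(0, cumsum(is_c))
    cum_g <- c(0, cumsum(is_g))
    cum_cg <- c(0, cumsum(is_cg))
    starts <- seq(1L, L - window + 1L, by = step)   # 1-based window starts
    nC <- cum_c[starts + window] - cum_c[starts]
    nG <- cum_g[starts + window] - cum_g[starts]
    # CpG dinucleotides fully inside the window
    nCG <- cum_cg[starts + window - 1L] - cum_cg[starts]
    gc <- (nC + nG) / window
    oe <- ifelse(nC * nG > 0, nCG * window / (nC * nG), 0)
    ok <- gc >= gc_min & oe >= oe_min
    if (!any(ok)) next
    # union of qualifying windows via a coverage-difference vector
    delta <- integer(L + 1L)
    ws <- starts[ok]
    delta[ws] <- delta[ws] + 1L
    we <- ws + window
    we[we > L + 1L] <- L + 1L
    tab <- table(we)
    delta[as.integer(names(tab))] <-
      delta[as.integer(names(tab))] - as.integer(tab)
    covered <- cumsum(delta[seq_len(L)]) > 0
    r <- rle(covered)
    ends <- cumsum(r$lengths)
    seg_s <- (ends - r$lengths)[r$values]   # 0-based
    seg_e <- ends[r$values]
    for (k in seq_along(seg_s)) {
      a <- seg_s[k]; b <- seg_e[k]
      len <- b - a
      if (len < min_length) next
      nC2 <- cum_c[b + 1] - cum_c[a + 1]
      nG2 <- cum_g[b + 1] - cum_g[a + 1]
      nCG2 <- cum_cg[b] - cum_cg[a + 1]
      gc2 <- (nC2 + nG2) / len
      oe2 <- if (nC2 * nG2 > 0) nCG2 * len / (nC2 * nG2) else 0
      if (gc2 >= gc_min && oe2 >= oe_min)
        res[[length(res) + 1]] <-
          data.frame(chrom = cn, start = a, end = b, length = len,
                     gc_fraction = gc2, obs_exp_cpg = oe2,
                     stringsAsFactors = FALSE)
    }
  }
  if (!length(res))
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), length = integer(),
                      gc_fraction = numeric(), obs_exp_cpg = numeric()))
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Flag novel transcripts with a CpG island near the putative promoter
#'
#' `TRUE` iff any island lies within `dist` bp (either direction) of the
#' candidate's TSS; an island containing the TSS counts as distance 0.
#'
#' @param novel data.frame with `chrom` and `tss` columns.
#' @param islands result of [find_cpg_islands()].
#' @param dist distance threshold in bp (default 1000, inclusive).
#' @return logical vector, one per row of `novel`.
#' @export
promoter_cpg_flag <- function(novel, islands, dist = 1000L) {
  vapply(seq_len(nrow(novel)), function(i) {
    isl <- islands[islands$chrom == novel$chrom[i], , drop = FALSE]
    if (!nrow(isl)) return(FALSE)
    tss <- novel$tss[i]
    inside <- tss >= isl$start & tss < isl$end
    d <- pmin(abs(isl$start - tss), abs(tss - (isl$end - 1L)))
    d[inside] <- 0L
    any(d <= dist)
  }, TRUE)
}

#' ORF-based coding-potential score
#'
#' Longest open reading frame (ATG through the next in-frame stop codon,
#' any of the three forward frames), as a fraction of the transcript
#' length. Scores below `0.3` are conventionally treated as low coding
#' potential (non-coding).
#'
#' @param sequence single transcript sequence (character scalar, A/C/G/T/N).
#' @return score in `[0, 1]`.
#' @export
coding_potential <- function(sequence) {
  s <- toupper(sequence)
  L <- nchar(s)
  if (L < 60) stop("sequence shorter than 60 nt")
  best <- 0L
  stops <- c("TAA", "TAG", "TGA")
  for (frame in 0:2) {
    n_codon <- (L - frame) %/% 3
    if (n_codon < 2) next
    codons <- substring(s, frame + 1 + 3 * (0:(n_codon - 1)),
                        frame + 3 * (1:n_codon))
    atg <- which(codons == "ATG")
    stp <- which(codons %in% stops)
    if (!length(atg) || !length(stp)) next
    nxt <- stp[findInterval(atg, stp) + 1L]
    valid <- !is.na(nxt)
    if (any(valid)) {
      orf <- (nxt[valid] - atg[valid] + 1L) * 3L
      best <- max(best, max(orf))
    }
  }
  best / L
}

#' Classify sense/antisense regulation pairing
#'
#' For an antisense novel transcript and its overlapping sense partner:
#' when both log2 fold-changes are at least `delta` in magnitude, equal
#' signs mean co-regulation and opposite signs counter-regulation;
#' otherwise the pair is unclassified.
#'
#' @param antisense_lfc,sense_lfc log2 fold-changes (scalars or vectors).
#' @param delta magnitude threshold (default 0.5 log2 units).
#' @return character vector in `c("co_regulated", "counter_regulated",
#'   "unclassified")`.
#' @export
pair_regulation <- function(antisense_lfc, sense_lfc, delta = 0.5) {
  strong <- abs(antisense_lfc) >= delta & abs(sense_lfc) >= delta
  same <- sign(antisense_lfc) == sign(sense_lfc)
  ifelse(strong & same, "co_regulated",
  ifelse(strong & !same, "counter_regulated", "unclassified"))
}

#' Normalized coverage abundance of intervals (per million of track signal)
#'
#' Utility used to quantify assembled candidates from stranded coverage:
#' the summed signal over the interval as parts-per-million of the total
#' track signal — a count-like quantity on the same scale as CPM, so the
#' same fold-change pseudocount applies.
#'
#' @param intervals interval data.frame with `chrom`, `start`, `end`,
#'   `strand`.
#' @param tracks named list of [coverage_track()]s by strand.
#' @return numeric vector of normalized abundances.
#' @export
coverage_abundance <- function(intervals, tracks) {
  vapply(seq_len(nrow(intervals)), function(i) {
    tr <- tracks[[intervals$strand[i]]]
    v <- tr$values[[intervals$chrom[i]]]
    s <- sum(v[(intervals$start[i] + 1L):intervals$end[i]])
    if (tr$total_signal > 0) s * 1e6 / tr$total_signal else 0
  }, 1)
}

#' Full annotation of assembled novel transcript candidates
#'
#' Runs [classify_novel()], extracts candidate sequences, scores coding
#' potential, flags promoter-proximal CpG islands and (when expression
#' information is supplied) attaches log2 fold-changes and the
#' sense/antisense regulation pairing.
#'
#' @param candidates from [assemble_unexplained()].
#' @param annotation public transcript table.
#' @param genome named character vector of chromosome sequences.
#' @param islands optional precomputed [find_cpg_islands()] result
#'   (computed from `genome` if `NULL`).
#' @param novel_lfc optional named numeric: log2FC per candidate id.
#' @param expr optional [expression_table()] (for sense-partner log2FC).
#' @param delta pairing threshold, see [pair_regulation()].
#' @param coding_threshold score below which a candidate counts as
#'   non-coding (default 0.3).
#' @return data.frame with all novel-transcript fields.
#' @export
annotate_novel <- function(candidates, annotation, genome, islands = NULL,
                           novel_lfc = NULL, expr = NULL, delta = 0.5,
                           coding_threshold = 0.3) {
  out <- classify_novel(candidates, annotation)
  if (!nrow(out)) return(out)
  if (is.null(islands)) islands <- find_cpg_islands(genome)
  out$cpg_within_1kb <- promoter_cpg_flag(out, islands)
  out$coding_potential <- vapply(seq_len(nrow(out)), function(i) {
    seq_i <- substr(genome[[out$chrom[i]]], out$start[i] + 1L, out$end[i])
    coding_potential(seq_i)
  }, 1)
  out$low_coding_potential <- out$coding_potential < coding_threshold
  out$log2FC <- if (!is.null(novel_lfc)) unname(novel_lfc[out$id])
                else NA_real_
  out$regulation_pair <- NA_character_
  if (!is.null(expr)) {
    is_as <- out$category == "antisense"
    sense_lfc <- expr$lfc_hypoxia[match(out$overlapping_sense_id, expr$id)]
    out$regulation_pair[is_as] <-
      pair_regulation(out$log2FC[is_as], sense_lfc[is_as], delta)
  }
  out
}
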