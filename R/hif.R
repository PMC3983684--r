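#' Assign each peak to the nearest expressed promoter
#'
#' Distance is measured from the peak summit to the TSS of the nearest
#' expressed transcript (peak strand is ignored; peaks are unstranded).
#' Equidistant TSSs are resolved toward the transcript with higher
#' abundance, then the lexicographically smaller id. The signed distance is
#' reported in transcript orientation: negative means the summit lies
#' upstream of the TSS.
#'
#' @param peaks peak data.frame (see [read_peaks()]).
#' @param expressed transcript table of expressed transcripts.
#' @param abundance optional named numeric (e.g. mean CPM) used for
#'   tie-breaking; transcripts missing from it count as abundance 0.
#' @return data.frame: `peak_id`, `factor`, `transcript_id`, `rna_class`,
#'   `distance` (signed), `abs_distance`. Peaks on chromosomes without any
#'   expressed transcript are dropped with a warning.
#' @export
nearest_expressed_promoter <- function(peaks, expressed, abundance = NULL) {
  if (nrow(expressed) == 0) stop("expressed transcript set is empty")
  ab <- if (is.null(abundance)) setNames(numeric(0), character(0))
        else abundance
  rows <- vector("list", nrow(peaks))
  for (cn in unique(peaks$chrom)) {
    tx <- expressed[expressed$chrom == cn, , drop = FALSE]
    pk_idx <- which(peaks$chrom == cn)
    if (!nrow(tx)) next
    # order TSS; resolve exact-distance ties by abundance then id
    tx$ab <- ifelse(is.na(ab[tx$id]), 0, ab[tx$id])
    o <- order(tx$tss)
    tss <- tx$tss[o]
    for (j in pk_idx) {
      s <- peaks$summit[j]
      k <- findInterval(s, tss)
      cand <- unique(pmin(pmax(c(k, k + 1L), 1L), length(tss)))
      d <- abs(tss[cand] - s)
      dmin <- min(d)
      # all transcripts whose TSS achieves the minimum distance
      at <- which(abs(tx$tss - s) == dmin)
      pick <- at[order(-tx$ab[at], tx$id[at])][1]
      signed <- if (tx$strand[pick] == "+") s - tx$tss[pick]
                else tx$tss[pick] - s
      rows[[j]] <- data.frame(peak_id = peaks$id[j],
                              factor = peaks$factor[j],
                              transcript_id = tx$id[pick],
                              rna_class = tx$rna_class[pick],
                              distance = signed, abs_distance = dmin,
                              stringsAsFactors = FALSE)
    }
  }
  dropped <- sum(vapply(rows, is.null, TRUE))
  if (dropped > 0)
    warning(dropped, " peak(s) on chromosomes without expressed ",
            "transcripts were dropped")
  do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
}

#' Summarise peak-to-promoter distances
#'
#' Per factor: a histogram of absolute summit-to-TSS distances over
#' log-spaced bins, and the fraction of peaks lying beyond `cutoff` bp.
#'
#' @param assignments result of [nearest_expressed_promoter()].
#' @param cutoff distal threshold in bp (default 2500).
#' @param breaks histogram bin edges (bp); the last bin is open-ended.
#' @return list per factor with `n`, `fraction_distal` and `histogram`
#'   (data.frame `bin_lo`, `bin_hi`, `count`).
#' @export
distance_summary <- function(assignments, cutoff = 2500,
                             breaks = c(0, 10^seq(2, 6, by = 0.5), Inf)) {
  out <- list()
  for (f in unique(assignments$factor)) {
    d <- assignments$abs_distance[assignments$factor == f]
    if (!length(d)) stop("no assignments for factor ", f)
    h <- hist(pmin(d, max(breaks[is.finite(breaks)]) + 1),
              breaks = breaks, plot = FALSE, right = FALSE)
    out[[f]] <- list(
      n = length(d),
      fraction_distal = mean(d > cutoff),
      histogram = data.frame(bin_lo = breaks[-length(breaks)],
                             bin_hi = breaks[-1], count = h$counts))
  }
  out
}

#' Per-factor share of nearest-transcript RNA classes
#'
#' @param assignments result of [nearest_expressed_promoter()].
#' @return data.frame: `factor`, `rna_class`, `n`, `share` (shares sum to 1
#'   within each factor).
#' @export
class_proportions <- function(assignments) {
  rows <- list()
  for (f in unique(assignments$factor)) {
    sub <- assignments[assignments$factor == f, , drop = FALSE]
    tab <- table(sub$rna_class)
    rows[[f]] <- data.frame(factor = f, rna_class = names(tab),
                            n = as.integer(tab),
                            share = as.numeric(tab) / nrow(sub),
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# weighted Kolmogorov-Smirnov running-sum enrichment score
.gsea_running <- function(hit, score, weight_p) {
  n <- length(hit)
  nh <- sum(hit)
  w <- abs(score)^weight_p
  nr <- sum(w[hit])
  inc <- numeric(n)
  inc[hit] <- if (nr > 0) w[hit] / nr else 1 / nh
  inc[!hit] <- -1 / (n - nh)
  cumsum(inc)
}

#' Gene-set enrichment by weighted running sum with a permutation null
#'
#' Transcripts are ranked by a score (hypoxic induction); walking down the
#' ranking, set members add their normalized weighted score
#' (`|score|^weight_p`, normalized by the total hit weight) and non-members
#' subtract `1/(N - Nh)`. The enrichment score (ES) is the signed extremum
#' of the running sum. The null distribution comes from random gene-label
#' sets of equal size (the design has no replicate samples to permute);
#' the p-value is `(1 + #{|ES_perm| >= |ES_obs| with the same sign}) /
#' (1 + n_perm)`. The leading edge contains the set members at or before
#' the extremum (at or after it, for negative ES).
#'
#' @param ranked data.frame with `id` and the ranking score column, already
#'   ordered best-first (e.g. from [rank_by_induction()]).
#' @param gene_set character vector of member ids.
#' @param weight_p score weighting exponent (default 1; 0 gives the
#'   unweighted Kolmogorov-Smirnov statistic).
#' @param n_perm number of label permutations (default 1000).
#' @param seed RNG seed for the permutations.
#' @param score_col ranking score column name.
#' @return list of class `gsea_result`: `es`, `p_value`, `n_perm`,
#'   `leading_edge`, `seed`, `set_size`, `n`.
#' @export
gsea <- function(ranked, gene_set, weight_p = 1, n_perm = 1000L,
                 seed = 1L, score_col = "lfc_hypoxia") {
  ids <- ranked$id
  score <- ranked[[score_col]]
  hit <- ids %in% gene_set
  nh <- sum(hit)
  if (nh == 0 || nh == length(ids))
    stop("gene set must be a non-empty proper subset of the ranking")
  run <- .gsea_running(hit, score, weight_p)
  i_ext <- which.max(abs(run))
  es <- run[i_ext]
  set.seed(seed)
  n_extreme <- 0L
  for (b in seq_len(n_perm)) {
    ph <- logical(length(ids))
    ph[sample.int(length(ids), nh)] <- TRUE
    pr <- .gsea_running(ph, score, weight_p)
    pe <- pr[which.max(abs(pr))]
    if (sign(pe) == sign(es) && abs(pe) >= abs(es))
      n_extreme <- n_extreme + 1L
  }
  leading <- if (es >= 0) ids[seq_len(i_ext)][hit[seq_len(i_ext)]]
             else ids[i_ext:length(ids)][hit[i_ext:length(ids)]]
  structure(list(es = es, p_value = (1 + n_extreme) / (1 + n_perm),
                 n_perm = n_perm, leading_edge = leading, seed = seed,
                 set_size = nh, n = length(ids)),
            class = "gsea_result")
}

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("<gsea_result> ES = %.3f, p = %.4g (%d permutations)\n",
              x$es, x$p_value, x$n_perm))
  cat(sprintf("  set size %d of %d ranked; leading edge %d\n",
              x$set_size, x$n, length(x$leading_edge)))
  invisible(x)
}
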