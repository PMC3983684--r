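#' The n transcripts most upregulated by hypoxia
#'
#' A prefix of [rank_by_induction()] over all classes.
#'
#' @param expr an [expression_table()] result.
#' @param n list size (default 100).
#' @return character vector of transcript ids, best first.
#' @export
select_top_induced <- function(expr, n = 100L) {
  ranked <- rank_by_induction(expr)
  if (nrow(ranked) < n)
    stop("only ", nrow(ranked), " transcripts available, need ", n)
  ranked$id[seq_len(n)]
}

#' Metagene profile around the TSS
#'
#' Mean signal per bin over a fixed window anchored at each gene's TSS and
#' oriented 5'->3' (minus-strand windows are reversed so "downstream" is
#' always the transcript's 3' direction). With `normalize = TRUE`, bin
#' values are scaled to fragments per kilobase per million:
#' `bin signal x 1e9 / (bin_size x total track signal)`, averaged over
#' genes; `normalize = FALSE` returns raw mean per-base signal (linear in
#' the track, used for additivity checks).
#'
#' @param track a [coverage_track()].
#' @param genes transcript table rows to average over.
#' @param window `c(upstream, downstream)` bp around the TSS
#'   (default `c(-2000, 2000)`).
#' @param bin_size bp per bin (default 10; must divide the window span).
#' @param normalize scale to per-kb per-million units (default TRUE).
#' @return data.frame of class `metagene_profile`: `bin_centre` (bp from
#'   TSS) and `value`; attributes `mark`, `condition`, `n_genes`.
#' @export
metagene <- function(track, genes, window = c(-2000L, 2000L),
                     bin_size = 10L, normalize = TRUE) {
  if (nrow(genes) == 0) stop("empty gene list")
  span <- window[2] - window[1]
  if (span %% bin_size != 0) stop("bin_size must divide the window span")
  n_bins <- span %/% bin_size
  offs <- window[1]:(window[2] - 1L)
  acc <- numeric(n_bins)
  used <- 0L
  for (i in seq_len(nrow(genes))) {
    v <- track$values[[genes$chrom[i]]]
    dir <- if (genes$strand[i] == "+") 1L else -1L
    pos <- genes$tss[i] + dir * offs + 1L
    if (min(pos) < 1L || max(pos) > length(v)) {
      warning("gene ", genes$id[i], " too close to a chromosome edge; ",
              "skipped")
      next
    }
    sig <- v[pos]
    acc <- acc + colSums(matrix(sig, nrow = bin_size))
    used <- used + 1L
  }
  if (used == 0L) stop("no gene had a complete window")
  vals <- acc / used
  if (normalize) {
    if (track$total_signal <= 0) stop("track has zero total signal")
    vals <- vals * 1e9 / (bin_size * track$total_signal)
  } else {
    vals <- vals / bin_size
  }
  out <- data.frame(
    bin_centre = window[1] + bin_size * (seq_len(n_bins) - 1L) +
      bin_size / 2,
    value = vals)
  attr(out, "mark") <- track$mark
  attr(out, "condition") <- track$condition
  attr(out, "n_genes") <- used
  class(out) <- c("metagene_profile", "data.frame")
  out
}

#' Offset of the pause summit from the TSS
#'
#' Centre of the maximum bin of a metagene profile; ties resolve to the
#' smallest offset. A flat profile has no summit and is an error.
#'
#' @param profile a [metagene()] result.
#' @return offset in bp (bin centre) of the profile maximum.
#' @export
pause_summit_offset <- function(profile) {
  v <- profile$value
  if (diff(range(v)) == 0) stop("flat profile has no summit")
  at <- which(v == max(v))
  at <- at[order(abs(profile$bin_centre[at]))][1]
  profile$bin_centre[at]
}

#' Travelling ratio per transcript
#'
#' Ratio of mean RNApol2 signal density in the promoter-proximal window
#' (TSS-30 to TSS+300, transcript orientation) to the density over the gene
#' body (TSS+300 to the transcript end). High values indicate
#' promoter-proximal pausing. Transcripts shorter than 330 bp have an empty
#' body window and are skipped with a warning; a zero body density gives an
#' undefined (NA) ratio, flagged in the output.
#'
#' @param track a [coverage_track()].
#' @param transcripts transcript table.
#' @param promoter_window `c(upstream, downstream)` bp around the TSS.
#' @param body_start bp downstream of the TSS where the body begins.
#' @return data.frame: `id`, `promoter_density`, `body_density`, `tr`,
#'   `undefined`, `condition`.
#' @export
travelling_ratio <- function(track, transcripts,
                             promoter_window = c(-30L, 300L),
                             body_start = 300L) {
  rows <- vector("list", nrow(transcripts))
  skipped <- 0L
  for (i in seq_len(nrow(transcripts))) {
    tx <- transcripts[i, ]
    if (tx$length <= body_start + 30L) { skipped <- skipped + 1L; next }
    v <- track$values[[tx$chrom]]
    dir <- if (tx$strand == "+") 1L else -1L
    p_off <- promoter_window[1]:(promoter_window[2] - 1L)
    b_off <- body_start:(tx$length - 1L)
    p_pos <- tx$tss + dir * p_off + 1L
    b_pos <- tx$tss + dir * b_off + 1L
    p_pos <- p_pos[p_pos >= 1 & p_pos <= length(v)]
    b_pos <- b_pos[b_pos >= 1 & b_pos <= length(v)]
    pd <- mean(v[p_pos])
    bd <- mean(v[b_pos])
    rows[[i]] <- data.frame(id = tx$id, promoter_density = pd,
                            body_density = bd,
                            tr = if (bd > 0) pd / bd else NA_real_,
                            undefined = bd == 0,
                            condition = track$condition,
                            stringsAsFactors = FALSE)
  }
  if (skipped > 0)
    warning(skipped, " transcript(s) shorter than the body window were ",
            "skipped")
  out <- do.call(rbind, rows[!vapply(rows, is.null, TRUE)])
  rownames(out) <- NULL
  out
}

#' Wilcoxon rank-sum statistic (normal approximation, tie-corrected)
#'
#' Two-sided test that two samples come from the same distribution, using
#' the rank-sum W of `x` with a continuity-corrected normal approximation
#' and the standard tie correction of the variance.
#'
#' @param x,y numeric vectors.
#' @return list: `w` (rank-sum statistic, Mann-Whitney form), `z`,
#'   `p_value`.
#' @export
rank_sum_test <- function(x, y) {
  n1 <- length(x); n2 <- length(y)
  if (n1 == 0 || n2 == 0) stop("empty sample")
  r <- rank(c(x, y))
  w <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  n <- n1 + n2
  ties <- table(r)
  tie_term <- sum(ties^3 - ties) / (n * (n - 1))
  sigma2 <- n1 * n2 / 12 * ((n + 1) - tie_term)
  if (sigma2 == 0) return(list(w = w, z = 0, p_value = 1))
  z <- (w - mu - sign(w - mu) * 0.5) / sqrt(sigma2)
  list(w = w, z = z, p_value = min(1, 2 * stats::pnorm(-abs(z))))
}

#' Travelling-ratio shift between conditions, by gene group
#'
#' For each gene, `dlogTR = log2(TR_hypoxia) - log2(TR_normoxia)`; pause
#' release lowers the TR, so direct HIF targets are expected to shift
#' negative while genes far from any HIF peak should not move. Reports the
#' median shift per group and a rank-sum test comparing the first (target)
#' group against the second (control) group.
#'
#' @param tr_normoxia,tr_hypoxia [travelling_ratio()] results for the two
#'   conditions (matched on `id`).
#' @param gene_groups named list of character id vectors; the first two
#'   groups are compared.
#' @param min_group_size groups smaller than this are an error (default 5).
#' @return list: `per_group` (data.frame `group`, `n`, `median_dlogTR`),
#'   `w`, `z`, `p_value`.
#' @export
tr_shift <- function(tr_normoxia, tr_hypoxia, gene_groups,
                     min_group_size = 5L) {
  if (length(gene_groups) < 2 || is.null(names(gene_groups)))
    stop("gene_groups must be a named list with at least two groups")
  shared <- intersect(tr_normoxia$id, tr_hypoxia$id)
  tn <- tr_normoxia[match(shared, tr_normoxia$id), ]
  th <- tr_hypoxia[match(shared, tr_hypoxia$id), ]
  ok <- !tn$undefined & !th$undefined & tn$tr > 0 & th$tr > 0
  dlog <- setNames(log2(th$tr[ok]) - log2(tn$tr[ok]), shared[ok])
  vals <- lapply(gene_groups, function(g) dlog[intersect(g, names(dlog))])
  sizes <- lengths(vals)
  if (any(sizes < min_group_size))
    stop("group(s) below minimum size ", min_group_size, ": ",
         paste(names(gene_groups)[sizes < min_group_size], collapse = ", "))
  per_group <- data.frame(group = names(vals), n = sizes,
                          median_dlogTR = vapply(vals, median, 1),
                          row.names = NULL, stringsAsFactors = FALSE)
  test <- rank_sum_test(vals[[1]], vals[[2]])
  c(list(per_group = per_group), test)
}

#' Classify hypoxic induction mode from promoter and body densities
#'
#' Compares promoter and gene-body RNApol2 densities between conditions
#' (pseudocount 0.1 signal/bp): a body increase of at least `body_fold`
#' with a promoter increase below `promoter_stable_fold` is pause release;
#' a body increase with a promoter increase of at least `promoter_fold` is
#' de novo recruitment; everything else (including intermediate promoter
#' behaviour) is unchanged.
#'
#' @param tr_normoxia,tr_hypoxia [travelling_ratio()] results (matched ids).
#' @param body_fold minimum body-density fold increase (default 2).
#' @param promoter_stable_fold promoter fold below which the promoter
#'   counts as unchanged (default 1.5).
#' @param promoter_fold promoter fold at or above which recruitment is de
#'   novo (default 2).
#' @param pseudocount signal/bp added to all densities (default 0.1).
#' @return data.frame: `id`, `body_ratio`, `promoter_ratio`, `mode` in
#'   `c("pause_release", "de_novo_recruitment", "unchanged")`.
#' @export
classify_induction_mode <- function(tr_normoxia, tr_hypoxia, body_fold = 2,
                                    promoter_stable_fold = 1.5,
                                    promoter_fold = 2, pseudocount = 0.1) {
  shared <- intersect(tr_normoxia$id, tr_hypoxia$id)
  tn <- tr_normoxia[match(shared, tr_normoxia$id), ]
  th <- tr_hypoxia[match(shared, tr_hypoxia$id), ]
  br <- (th$body_density + pseudocount) / (tn$body_density + pseudocount)
  pr <- (th$promoter_density + pseudocount) /
        (tn$promoter_density + pseudocount)
  mode <- ifelse(br >= body_fold & pr < promoter_stable_fold,
                 "pause_release",
          ifelse(br >= body_fold & pr >= promoter_fold,
                 "de_novo_recruitment", "unchanged"))
  data.frame(id = shared, body_ratio = br, promoter_ratio = pr,
             mode = mode, stringsAsFactors = FALSE)
}
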