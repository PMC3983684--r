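#' Counts per million
#'
#' `cpm = count / lib_size * 1e6`, with library sizes taken from the count
#' matrix (column sums). Direction and ranking of fold-changes are what the
#' downstream class summaries and enrichment use; CPM preserves both when
#' library composition is near-balanced between conditions.
#'
#' @param counts a [count_matrix()].
#' @return numeric matrix of CPM values (same dimnames).
#' @export
normalize_cpm <- function(counts) {
  if (any(counts$lib_sizes <= 0))
    stop("zero library size; cannot normalize")
  sweep(counts$counts, 2, counts$lib_sizes, "/") * 1e6
}

#' Log2 fold-change with a pseudocount
#'
#' `log2((b + pc) / (a + pc))`, finite for all non-negative inputs.
#'
#' @param norm_a,norm_b normalized abundances (reference and test).
#' @param pseudocount added to both sides (CPM units; default 0.5).
#' @return numeric vector of log2 fold-changes (b vs a).
#' @export
log2_fold_change <- function(norm_a, norm_b, pseudocount = 0.5) {
  if (pseudocount <= 0) stop("pseudocount must be > 0")
  log2((norm_b + pseudocount) / (norm_a + pseudocount))
}

#' Build the per-transcript expression table
#'
#' CPM per sample plus log2 fold-changes for the standard contrasts:
#' hypoxia vs normoxia and each HIF siRNA vs the control siRNA (where those
#' samples are present).
#'
#' @param counts a [count_matrix()].
#' @param classes named character vector: class per transcript id.
#' @param pseudocount see [log2_fold_change()].
#' @return data.frame with `id`, `rna_class`, `cpm_<sample>` columns, a
#'   `mean_cpm` column over the hypoxia/normoxia pair, and
#'   `lfc_<contrast>` columns.
#' @export
expression_table <- function(counts, classes, pseudocount = 0.5) {
  cpm <- normalize_cpm(counts)
  ids <- rownames(cpm)
  out <- data.frame(id = ids, rna_class = unname(classes[ids]),
                    stringsAsFactors = FALSE)
  for (s in colnames(cpm)) out[[paste0("cpm_", s)]] <- cpm[, s]
  out$mean_cpm <- rowMeans(cpm[, intersect(c("normoxia", "hypoxia"),
                                           colnames(cpm)), drop = FALSE])
  contrasts <- list(hypoxia = c("normoxia", "hypoxia"),
                    siHIF1a = c("hypoxia_siControl", "hypoxia_siHIF1a"),
                    siHIF2a = c("hypoxia_siControl", "hypoxia_siHIF2a"),
                    siBoth = c("hypoxia_siControl", "hypoxia_siBoth"))
  for (nm in names(contrasts)) {
    cc <- contrasts[[nm]]
    if (all(cc %in% colnames(cpm)))
      out[[paste0("lfc_", nm)]] <-
        log2_fold_change(cpm[, cc[1]], cpm[, cc[2]], pseudocount)
  }
  out
}

#' Box-plot statistics of log2 fold-change per RNA class
#'
#' Median, quartiles (linear interpolation, the default quantile type) and
#' whisker minimum/maximum of the hypoxic log2 fold-change, per class.
#' Empty classes are omitted with a warning.
#'
#' @param expr an [expression_table()] result.
#' @param lfc_col which log2FC column to summarise.
#' @return data.frame: `rna_class`, `n`, `min`, `q1`, `median`, `q3`, `max`.
#' @export
summarize_by_class <- function(expr, lfc_col = "lfc_hypoxia") {
  if (!lfc_col %in% names(expr)) stop("no column ", lfc_col)
  present <- unique(expr$rna_class)
  rows <- lapply(present, function(cl) {
    v <- expr[[lfc_col]][expr$rna_class == cl]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("class ", cl, " has no fold-change values; omitted")
      return(NULL)
    }
    q <- unname(quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7))
    data.frame(rna_class = cl, n = length(v), min = q[1], q1 = q[2],
               median = q[3], q3 = q[4], max = q[5])
  })
  out <- do.call(rbind, rows)
  out[order(out$rna_class), , drop = FALSE]
}

#' Rank transcripts by hypoxic induction
#'
#' Descending log2 fold-change; ties broken by higher mean abundance, then
#' by id, so the ranking is deterministic.
#'
#' @param expr an [expression_table()] result (or any data.frame with `id`,
#'   the ranking column and `mean_cpm`).
#' @param classes optional class filter (keep only these classes).
#' @param lfc_col ranking column.
#' @return data.frame of the ranked transcripts (best first) with a `rank`
#'   column.
#' @export
rank_by_induction <- function(expr, classes = NULL,
                              lfc_col = "lfc_hypoxia") {
  if (!is.null(classes)) expr <- expr[expr$rna_class %in% classes, ,
                                      drop = FALSE]
  o <- order(-expr[[lfc_col]], -expr$mean_cpm, expr$id)
  out <- expr[o, , drop = FALSE]
  out$rank <- seq_len(nrow(out))
  rownames(out) <- NULL
  out
}

#' siRNA-dependence matrix for HIF-binding transcripts
#'
#' One row per HIF-binding transcript (of an optional class filter):
#' log2 fold-changes for hypoxia and each siRNA contrast, plus a
#' HIF-dependence call. A transcript is called `HIF1` when the HIF-1a siRNA
#' suppresses it by at least `delta` log2 units while the HIF-2a siRNA does
#' not (mirrored for `HIF2`); `both` when both siRNAs suppress it; `none`
#' otherwise.
#'
#' @param expr an [expression_table()] result with the siRNA contrasts.
#' @param hif_targets character vector of peak-assigned transcript ids.
#' @param classes optional class filter.
#' @param delta log2 suppression threshold (default 0.5).
#' @return data.frame: `id`, `rna_class`, `lfc_hypoxia`, `lfc_siHIF1a`,
#'   `lfc_siHIF2a`, `lfc_siBoth`, `hif_call`.
#' @export
sirna_matrix <- function(expr, hif_targets, classes = NULL, delta = 0.5) {
  need <- c("lfc_siHIF1a", "lfc_siHIF2a", "lfc_siBoth")
  missing <- setdiff(need, names(expr))
  if (length(missing))
    stop("missing siRNA contrast column(s): ",
         paste(missing, collapse = ", "))
  rows <- expr[expr$id %in% hif_targets, , drop = FALSE]
  if (!is.null(classes)) rows <- rows[rows$rna_class %in% classes, ,
                                      drop = FALSE]
  s1 <- rows$lfc_siHIF1a <= -delta
  s2 <- rows$lfc_siHIF2a <= -delta
  call <- ifelse(s1 & s2, "both",
          ifelse(s1, "HIF1",
          ifelse(s2, "HIF2", "none")))
  data.frame(id = rows$id, rna_class = rows$rna_class,
             lfc_hypoxia = rows$lfc_hypoxia,
             lfc_siHIF1a = rows$lfc_siHIF1a,
             lfc_siHIF2a = rows$lfc_siHIF2a,
             lfc_siBoth = rows$lfc_siBoth,
             hif_call = call, stringsAsFactors = FALSE)
}

#' Spearman correlation of abundances between two platforms
#'
#' Rank correlation (average ranks for ties) over the transcripts shared by
#' both named vectors.
#'
#' @param norm_x,norm_y named numeric vectors of normalized abundances.
#' @return Spearman rho in `[-1, 1]`.
#' @export
platform_concordance <- function(norm_x, norm_y) {
  shared <- intersect(names(norm_x), names(norm_y))
  if (length(shared) < 3)
    stop("need at least 3 shared transcripts (have ", length(shared), ")")
  cor(norm_x[shared], norm_y[shared], method = "spearman")
}
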