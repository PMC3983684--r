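#' Pipeline configuration
#'
#' One flat configuration covering every stage, with the simulation
#' settings nested as a [sim_config()]. All tunable parameters of the
#' analysis stages are exposed here.
#'
#' @param seed master seed; the simulation and every stochastic stage
#'   derive their seeds from it.
#' @param sim a [sim_config()] (defaults to `sim_config(seed = seed)`).
#' @param pseudocount CPM pseudocount for fold-changes.
#' @param delta log2 threshold for siRNA dependence and sense/antisense
#'   pairing calls.
#' @param min_depth,max_gap,min_length assembler settings (the default
#'   `min_depth` sits well below the coverage of the faintest simulated
#'   transcript).
#' @param thresholds per-class abundance thresholds (`NULL` = class-length
#'   defaults, see [default_thresholds()]).
#' @param n_perm,weight_p GSEA settings.
#' @param top_n metagene gene-list size.
#' @param proximal_bp summit-to-TSS distance defining a HIF-bound promoter.
#' @param distal_control_bp minimum distance from any peak for the distal
#'   control gene group.
#' @param coding_threshold see [annotate_novel()].
#' @param stages character vector of stages to run, in dependency order.
#' @return list of class `pipeline_config`.
#' @export
pipeline_config <- function(seed = 1L, sim = sim_config(seed = seed),
                            pseudocount = 0.5, delta = 0.5,
                            min_depth = 0.02, max_gap = 100L,
                            min_length = 200L, thresholds = NULL,
                            n_perm = 1000L, weight_p = 1, top_n = 100L,
                            proximal_bp = 2500L, distal_control_bp = 1e6,
                            coding_threshold = 0.3,
                            stages = c("simulate", "classify", "express",
                                       "novel", "hif", "pausing",
                                       "report")) {
  structure(as.list(environment()), class = "pipeline_config")
}

.need <- function(outdir, stage, ...) {
  paths <- file.path(outdir, c(...))
  missing <- paths[!file.exists(paths)]
  if (length(missing))
    stop("stage '", stage, "' is missing input(s): ",
         paste(basename(missing), collapse = ", "))
  paths
}

.strand_tracks <- function(outdir, condition, chrom_sizes) {
  list("+" = read_coverage(
         file.path(outdir, sprintf("rnaseq_%s_plus.bedgraph", condition)),
         "RNAseq", condition, chrom_sizes, strand = "+"),
       "-" = read_coverage(
         file.path(outdir, sprintf("rnaseq_%s_minus.bedgraph", condition)),
         "RNAseq", condition, chrom_sizes, strand = "-"))
}

# minimum |TSS - summit| per transcript over all peaks (Inf on peak-free
# chromosomes)
.gene_peak_distance <- function(tx, peaks) {
  vapply(seq_len(nrow(tx)), function(i) {
    s <- peaks$summit[peaks$chrom == tx$chrom[i]]
    if (!length(s)) Inf else min(abs(s - tx$tss[i]))
  }, 1)
}

#' Run the full analysis pipeline
#'
#' Stages run in dependency order (simulate, classify, express, novel,
#' hif, pausing, report); each stage reads its inputs from `outdir` and
#' writes its outputs there, so any stage can be rerun from the on-disk
#' artifacts of its predecessors. A JSON manifest records the package
#' version, seed, parameters and per-stage output row counts. Reruns with
#' the same configuration reproduce byte-identical data outputs.
#'
#' @param config a [pipeline_config()].
#' @param outdir working/output directory.
#' @return (invisibly) the manifest list.
#' @export
run_pipeline <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  manifest <- list(package = "hypoxtx",
                   version = as.character(utils::packageVersion("hypoxtx")),
                   seed = config$seed,
                   parameters = config[setdiff(names(config), "sim")],
                   sim = unclass(config$sim),
                   stages = list())
  counts_of <- function(x) if (is.data.frame(x)) nrow(x) else as.numeric(x)

  for (stage in config$stages) {
    rc <- switch(stage,
      simulate = {
        simulate_dataset(config$sim, outdir)
        length(list.files(outdir))
      },
      classify = {
        .need(outdir, stage, "annotation.gtf", "counts.tsv")
        ann <- read_annotation(p("annotation.gtf"), "GTF")
        counts <- read_counts(p("counts.tsv"))
        cls <- classify_all(ann, ann)
        classes <- setNames(ann$rna_class, ann$id)
        thr <- if (is.null(config$thresholds)) default_thresholds(ann)
               else config$thresholds
        filtered <- filter_low_abundance(counts, classes, thr)
        write_counts(filtered, p("counts_filtered.tsv"))
        write_table(data.frame(rna_class = names(cls$per_class),
                               n_assigned = cls$per_class,
                               threshold = unname(thr[names(cls$per_class)])),
                    p("class_summary.tsv"))
        nrow(filtered$counts)
      },
      express = {
        .need(outdir, stage, "counts_filtered.tsv", "annotation.gtf")
        ann <- read_annotation(p("annotation.gtf"), "GTF")
        filtered <- read_counts(p("counts_filtered.tsv"))
        classes <- setNames(ann$rna_class, ann$id)
        expr <- expression_table(filtered, classes, config$pseudocount)
        write_table(expr, p("expression.tsv"))
        write_table(summarize_by_class(expr), p("class_fc_summary.tsv"))
        write_table(rank_by_induction(expr)[, c("id", "rna_class",
                                                "lfc_hypoxia", "mean_cpm",
                                                "rank")],
                    p("ranked.tsv"))
        nrow(expr)
      },
      novel = {
        .need(outdir, stage, "annotation.gtf", "chrom.sizes", "genome.fa",
              "rnaseq_hypoxia_plus.bedgraph", "expression.tsv")
        ann <- read_annotation(p("annotation.gtf"), "GTF")
        sizes <- read_chrom_sizes(p("chrom.sizes"))
        fa <- Biostrings::readDNAStringSet(p("genome.fa"))
        genome <- setNames(as.character(fa), names(fa))
        trk_n <- .strand_tracks(outdir, "normoxia", sizes)
        trk_h <- .strand_tracks(outdir, "hypoxia", sizes)
        # assemble on pooled-condition coverage so repressed loci are kept
        pooled <- lapply(c("+", "-"), function(st) {
          v <- mapply(`+`, trk_n[[st]]$values, trk_h[[st]]$values,
                      SIMPLIFY = FALSE)
          coverage_track(v, "RNAseq", "pooled", st)
        })
        names(pooled) <- c("+", "-")
        cand <- assemble_unexplained(pooled, ann,
                                     min_depth = config$min_depth,
                                     max_gap = config$max_gap,
                                     min_length = config$min_length)
        ab_n <- coverage_abundance(cand, trk_n)
        ab_h <- coverage_abundance(cand, trk_h)
        lfc <- setNames(log2_fold_change(ab_n, ab_h, config$pseudocount),
                        cand$id)
        expr <- read_table(p("expression.tsv"))
        novel <- annotate_novel(cand, ann, genome, novel_lfc = lfc,
                                expr = expr, delta = config$delta,
                                coding_threshold = config$coding_threshold)
        novel$mean_abundance <-
          (ab_n[match(novel$id, cand$id)] +
           ab_h[match(novel$id, cand$id)]) / 2
        write_table(novel, p("novel.tsv"))
        writeLines(sprintf("%s\t%d\t%d\t%s\t0\t%s", novel$chrom,
                           novel$start, novel$end, novel$id, novel$strand),
                   p("novel.bed"))
        nrow(novel)
      },
      hif = {
        .need(outdir, stage, "annotation.gtf", "counts_filtered.tsv",
              "expression.tsv", "novel.tsv", "peaks_hif1.bed",
              "peaks_hif2.bed")
        ann <- read_annotation(p("annotation.gtf"), "GTF")
        expr <- read_table(p("expression.tsv"))
        novel <- read_table(p("novel.tsv"))
        peaks <- rbind(read_peaks(p("peaks_hif1.bed"), "HIF1"),
                       read_peaks(p("peaks_hif2.bed"), "HIF2"))
        # pooled universe: filtered public transcripts + discovered novel
        pub <- ann[ann$id %in% expr$id, , drop = FALSE]
        nov_tx <- transcript_table(novel$id, novel$chrom, novel$start,
                                   novel$end, novel$strand,
                                   rep("novel", nrow(novel)))
        expressed <- rbind(pub[, names(nov_tx)], nov_tx)
        pooled <- rbind(
          data.frame(id = expr$id, rna_class = expr$rna_class,
                     lfc_hypoxia = expr$lfc_hypoxia,
                     mean_cpm = expr$mean_cpm),
          data.frame(id = novel$id, rna_class = "novel",
                     lfc_hypoxia = novel$log2FC,
                     mean_cpm = novel$mean_abundance))
        abundance <- setNames(pooled$mean_cpm, pooled$id)
        assign <- nearest_expressed_promoter(peaks, expressed, abundance)
        write_table(assign, p("peak_assignments.tsv"))
        ds <- distance_summary(assign, cutoff = config$proximal_bp)
        write_table(do.call(rbind, lapply(names(ds), function(f)
          cbind(factor = f, ds[[f]]$histogram,
                fraction_distal = ds[[f]]$fraction_distal,
                n = ds[[f]]$n))), p("peak_distances.tsv"))
        write_table(class_proportions(assign), p("peak_classes.tsv"))
        ranked <- rank_by_induction(pooled)
        hif_set <- unique(assign$transcript_id[assign$abs_distance <=
                                                 config$proximal_bp])
        res <- gsea(ranked, hif_set, weight_p = config$weight_p,
                    n_perm = config$n_perm, seed = config$seed + 101L)
        set.seed(config$seed + 103L)
        rand_set <- sample(ranked$id, length(hif_set))
        res_rand <- gsea(ranked, rand_set, weight_p = config$weight_p,
                         n_perm = config$n_perm, seed = config$seed + 105L)
        jsonlite::write_json(
          list(hif_binding = res[c("es", "p_value", "n_perm", "set_size",
                                   "seed")],
               random_matched = res_rand[c("es", "p_value", "n_perm",
                                           "set_size", "seed")],
               leading_edge = res$leading_edge),
          p("enrichment.json"), auto_unbox = TRUE, digits = NA)
        nrow(assign)
      },
      pausing = {
        .need(outdir, stage, "annotation.gtf", "chrom.sizes",
              "expression.tsv", "novel.tsv", "peak_assignments.tsv",
              "rnapol2_normoxia.bedgraph", "rnapol2_hypoxia.bedgraph")
        ann <- read_annotation(p("annotation.gtf"), "GTF")
        sizes <- read_chrom_sizes(p("chrom.sizes"))
        expr <- read_table(p("expression.tsv"))
        novel <- read_table(p("novel.tsv"))
        assign <- read_table(p("peak_assignments.tsv"))
        peaks <- rbind(read_peaks(p("peaks_hif1.bed"), "HIF1"),
                       read_peaks(p("peaks_hif2.bed"), "HIF2"))
        nov_tx <- transcript_table(novel$id, novel$chrom, novel$start,
                                   novel$end, novel$strand,
                                   rep("novel", nrow(novel)))
        all_tx <- rbind(ann[, names(nov_tx)], nov_tx)
        pooled <- rbind(
          data.frame(id = expr$id, rna_class = expr$rna_class,
                     lfc_hypoxia = expr$lfc_hypoxia,
                     mean_cpm = expr$mean_cpm),
          data.frame(id = novel$id, rna_class = "novel",
                     lfc_hypoxia = novel$log2FC,
                     mean_cpm = novel$mean_abundance))
        top <- rank_by_induction(pooled)$id[seq_len(
          min(config$top_n, nrow(pooled)))]
        top_tx <- all_tx[all_tx$id %in% top, , drop = FALSE]
        tracks <- list()
        prof_rows <- list()
        for (mk in c("rnapol2", "h3k4me3", "dnase")) {
          mark <- c(rnapol2 = "RNApol2", h3k4me3 = "H3K4me3",
                    dnase = "DNase")[[mk]]
          for (cond in c("normoxia", "hypoxia")) {
            fn <- sprintf("%s_%s.bedgraph", mk, cond)
            if (!file.exists(p(fn))) next
            tr <- read_coverage(p(fn), mark, cond, sizes)
            if (mk == "rnapol2") tracks[[cond]] <- tr
            prof <- suppressWarnings(metagene(tr, top_tx))
            prof_rows[[paste(mk, cond)]] <-
              data.frame(mark = mark, condition = cond,
                         bin_centre = prof$bin_centre,
                         value = prof$value)
          }
        }
        prof_all <- do.call(rbind, prof_rows)
        write_table(prof_all[order(prof_all$mark, prof_all$condition,
                                   prof_all$bin_centre), ],
                    p("metagene.tsv"))
        pol2_hyp <- prof_all[prof_all$mark == "RNApol2" &
                             prof_all$condition == "hypoxia", ]
        class(pol2_hyp) <- c("metagene_profile", "data.frame")
        summit <- pause_summit_offset(pol2_hyp)
        long_tx <- all_tx[all_tx$length > 330, , drop = FALSE]
        tr_n <- suppressWarnings(travelling_ratio(tracks$normoxia, long_tx))
        tr_h <- suppressWarnings(travelling_ratio(tracks$hypoxia, long_tx))
        write_table(rbind(tr_n, tr_h), p("travelling_ratio.tsv"))
        direct <- unique(assign$transcript_id[assign$abs_distance <=
                                                config$proximal_bp])
        dist_to_peak <- .gene_peak_distance(long_tx, peaks)
        distal <- long_tx$id[dist_to_peak > config$distal_control_bp]
        shift <- tr_shift(tr_n, tr_h,
                          list(direct_targets = direct,
                               distal_controls = distal))
        modes <- classify_induction_mode(tr_n, tr_h)
        write_table(modes, p("induction_modes.tsv"))
        jsonlite::write_json(
          list(pause_summit_offset_bp = summit,
               tr_shift = list(per_group = shift$per_group,
                               w = shift$w, z = shift$z,
                               p_value = shift$p_value)),
          p("pausing_summary.json"), auto_unbox = TRUE, digits = NA)
        nrow(tr_n)
      },
      report = {
        report_tables(outdir)
      },
      stop("unknown stage: ", stage))
    manifest$stages[[stage]] <- list(rows = counts_of(rc))
    message("stage ", stage, " done")
  }
  jsonlite::write_json(manifest, p("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(manifest)
}

#' Collect figure-equivalent report tables
#'
#' A pure function of the on-disk stage outputs: writes one TSV per
#' figure-equivalent summary (class fold-change box statistics, peak class
#' proportions, peak distance histogram with distal fractions, metagene
#' bins, travelling-ratio distributions). Rerunning it changes nothing
#' else.
#'
#' @param outdir pipeline output directory.
#' @return number of report files written.
#' @export
report_tables <- function(outdir) {
  p <- function(...) file.path(outdir, ...)
  needed <- c("class_fc_summary.tsv", "peak_classes.tsv",
              "peak_distances.tsv", "metagene.tsv",
              "travelling_ratio.tsv")
  stage_of <- c(class_fc_summary.tsv = "express",
                peak_classes.tsv = "hif", peak_distances.tsv = "hif",
                metagene.tsv = "pausing", travelling_ratio.tsv = "pausing")
  for (f in needed)
    if (!file.exists(p(f)))
      stop("report needs output '", f, "' from stage '", stage_of[[f]],
           "' which has not run")
  n <- 0L
  for (f in needed) {
    write_table(read_table(p(f)), p(paste0("report_", f)))
    n <- n + 1L
  }
  n
}

#' Read / write a pipeline configuration as YAML
#'
#' One flat file, nested per module, so a whole run is reproducible from
#' the configuration and the seed alone.
#'
#' @param path YAML file path.
#' @return a [pipeline_config()].
#' @export
read_pipeline_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  y$sim <- NULL
  y$stages <- unlist(y$stages)
  cfg <- do.call(pipeline_config, y)
  if (!is.null(sim_args)) {
    if (!is.null(sim_args$class_counts))
      sim_args$class_counts <- unlist(sim_args$class_counts)
    if (!is.null(sim_args$class_effect))
      sim_args$class_effect <- unlist(sim_args$class_effect)
    if (!is.null(sim_args$distal_frac))
      sim_args$distal_frac <- unlist(sim_args$distal_frac)
    if (is.null(sim_args$seed)) sim_args$seed <- cfg$seed
    cfg$sim <- do.call(sim_config, sim_args)
  }
  cfg
}

#' @rdname read_pipeline_config
#' @param config a [pipeline_config()].
#' @export
write_pipeline_config <- function(config, path) {
  out <- unclass(config)
  out$sim <- unclass(out$sim)
  # named atomic vectors serialise as YAML maps, not bare sequences
  for (nm in c("class_counts", "class_effect", "distal_frac"))
    out$sim[[nm]] <- as.list(out$sim[[nm]])
  yaml::write_yaml(out, path)
  invisible(path)
}
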