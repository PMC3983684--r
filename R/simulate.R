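#' Simulation configuration
#'
#' Defaults describe a miniature hypoxia experiment with planted,
#' recoverable effects: class-specific hypoxic regulation (structural small
#' RNAs down, mRNA/lncRNA/miRNA up), a subset of strongly induced mRNA/lncRNA
#' transcripts that are HIF-1 and/or HIF-2 dependent with a binding peak near
#' their TSS, siRNA knockdown conditions, promoter-paused RNApol2 whose
#' gene-body signal rises in hypoxia at direct HIF targets, and planted
#' non-annotated intergenic and antisense loci (37 + 54, with a CpG island
#' planted upstream of 55% of them).
#'
#' Baseline-abundance ranges give the down-regulated structural classes
#' (snRNA/tRNA) a large share of library mass, as in real ribosome-depleted
#' total-RNA libraries; this keeps library composition near-balanced between
#' conditions, which the CPM normalisation downstream assumes.
#'
#' @param seed integer seed; every stochastic choice derives from it.
#' @param n_chroms,chrom_length genome shape (bp per chromosome).
#' @param class_counts named integer vector: public transcripts per class.
#' @param class_length named list of `c(min, max)` transcript lengths (bp).
#' @param class_effect named numeric: per-class mean log2 fold-change in
#'   hypoxia (novel loci use the `novel` entry).
#' @param effect_sd per-transcript SD around the class mean (log2 units).
#' @param class_base_mean named list of `c(min, max)` baseline mean counts
#'   (log-uniform draw).
#' @param frac_hif_targets fraction of strongly induced
#'   (log2FC >= `hif_target_min_lfc`) mRNA/lncRNA transcripts made
#'   HIF-dependent and given a nearby peak.
#' @param hif_target_min_lfc induction floor for HIF-target candidacy.
#' @param hif1_frac,hif2_frac shares of targets labelled HIF1-only and
#'   HIF2-only (remainder labelled `both`).
#' @param distal_frac named numeric (HIF1, HIF2): intended fraction of each
#'   factor's peaks lying > 2.5 kb from any promoter.
#' @param n_distal_peaks override for distal peak counts (`NULL` = derive
#'   from `distal_frac`).
#' @param peak_width peak interval width (bp).
#' @param dispersion negative-binomial dispersion (0 = Poisson).
#' @param knockdown_efficiency fraction of the HIF-attributable log2
#'   induction removed by the matching siRNA.
#' @param pause_offset bp downstream of the TSS of the RNApol2 pause summit.
#' @param pause_width Gaussian SD of the pause peak (bp).
#' @param pause_height,body_height pause and gene-body signal amplitudes
#'   (per unit relative expression).
#' @param body_start bp downstream of the TSS where gene-body signal
#'   begins (matches the travelling-ratio body window).
#' @param frac_de_novo fraction of HIF targets induced by de novo RNApol2
#'   recruitment rather than pause release.
#' @param n_novel_intergenic,n_novel_antisense planted novel locus counts.
#' @param novel_length_range intergenic novel locus length range (bp).
#' @param cpg_frac fraction of novel loci given a planted CpG island within
#'   1000 bp upstream of the TSS.
#' @param cpg_island_length planted island length (bp).
#' @param min_gap minimum same-strand gap between placed transcripts (bp);
#'   keep above the assembler's `max_gap` so merging cannot bridge loci.
#' @param edge_margin bp kept free at chromosome ends.
#' @param replicates biological replicates per condition (1, as in the
#'   original single-library design).
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chroms = 4L,
                       chrom_length = 2200000L,
                       class_counts = c(mRNA = 400L, lncRNA = 200L,
                                        miRNA = 120L, snRNA = 80L,
                                        tRNA = 80L, piwiRNA = 60L),
                       class_length = list(mRNA = c(2000, 20000),
                                           lncRNA = c(500, 10000),
                                           miRNA = c(60, 120),
                                           snRNA = c(70, 300),
                                           tRNA = c(70, 300),
                                           piwiRNA = c(70, 300)),
                       class_effect = c(mRNA = 0.3, lncRNA = 0.3,
                                        miRNA = 0.2, snRNA = -0.5,
                                        tRNA = -0.4, piwiRNA = -0.3,
                                        novel = 0.3),
                       effect_sd = 0.6,
                       class_base_mean = list(mRNA = c(30, 3000),
                                              lncRNA = c(30, 3000),
                                              miRNA = c(100, 2000),
                                              snRNA = c(200, 20000),
                                              tRNA = c(200, 20000),
                                              piwiRNA = c(100, 2000),
                                              novel = c(30, 1000)),
                       frac_hif_targets = 0.6,
                       hif_target_min_lfc = 1.2,
                       hif1_frac = 0.4,
                       hif2_frac = 0.4,
                       distal_frac = c(HIF1 = 0.5, HIF2 = 0.7),
                       n_distal_peaks = NULL,
                       peak_width = 300L,
                       dispersion = 0.02,
                       knockdown_efficiency = 0.9,
                       pause_offset = 42L,
                       pause_width = 35,
                       pause_height = 8,
                       body_height = 1,
                       body_start = 300L,
                       frac_de_novo = 0.15,
                       n_novel_intergenic = 37L,
                       n_novel_antisense = 54L,
                       novel_length_range = c(500, 10000),
                       cpg_frac = 0.55,
                       cpg_island_length = 500L,
                       min_gap = 400L,
                       edge_margin = 2500L,
                       replicates = 1L) {
  cfg <- as.list(environment())
  stopifnot(cfg$cpg_frac >= 0, cfg$cpg_frac <= 1,
            cfg$frac_hif_targets >= 0, cfg$frac_hif_targets <= 1,
            cfg$hif1_frac + cfg$hif2_frac <= 1,
            cfg$knockdown_efficiency >= 0, cfg$knockdown_efficiency <= 1,
            cfg$pause_offset >= 0, cfg$dispersion >= 0,
            all(cfg$class_counts >= 0), cfg$n_novel_intergenic >= 0,
            cfg$n_novel_antisense >= 0)
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config> seed", x$seed, "|", x$n_chroms, "chrom x",
      x$chrom_length, "bp |",
      sum(x$class_counts), "public +",
      x$n_novel_intergenic + x$n_novel_antisense, "novel transcripts\n")
  invisible(x)
}

.sim_chrom_sizes <- function(config) {
  setNames(rep(as.integer(config$chrom_length), config$n_chroms),
           paste0("chr", seq_len(config$n_chroms)))
}

.loguniform <- function(n, range) {
  exp(runif(n, log(range[1]), log(range[2])))
}

# Place transcripts without same-strand overlap: random gap allocation of
# the free space on each (chromosome, strand) lane.
.place_lane <- function(lens, lane_span, lane_offset, min_gap) {
  k <- length(lens)
  if (k == 0) return(integer())
  free <- lane_span - sum(lens) - (k + 1) * min_gap
  if (free < 0)
    stop("chrom_length too small to place requested transcripts ",
         "(need ", sum(lens) + (k + 1) * min_gap, " bp, have ",
         lane_span, ")")
  breaks <- sort(runif(k, 0, free))
  gaps <- min_gap + diff(c(0, breaks, free))
  starts <- lane_offset + cumsum(gaps[-(k + 1)]) + cumsum(c(0, lens[-k]))
  as.integer(round(starts))
}

#' Simulate the annotation, planted effects, novel loci and HIF peaks
#'
#' Public (annotated) transcripts are placed without same-strand overlap.
#' Planted antisense novel loci are contained in a sense mRNA on the
#' opposite strand; intergenic novel loci overlap nothing on either strand.
#' Each HIF-dependent transcript receives one peak per responsible factor
#' with its summit within 2.5 kb of the TSS; distal background peaks are
#' placed > 3 kb from every TSS. The last chromosome carries no peaks and
#' no HIF targets, providing a distal control gene group.
#'
#' @param config a [sim_config()].
#' @return list with `annotation` (public transcript table), `truth`
#'   (list: `effects` per-transcript data.frame, `novel` transcript table,
#'   `peaks` peak data.frame with `target_id`, `pause_offset`).
#' @export
simulate_annotation <- function(config) {
  set.seed(config$seed + 7L)
  sizes <- .sim_chrom_sizes(config)
  margin <- config$edge_margin
  lane_span <- config$chrom_length - 2 * margin

  cls <- rep(names(config$class_counts), config$class_counts)
  n_pub <- length(cls)
  lens <- vapply(cls, function(cl) {
    r <- config$class_length[[cl]]
    as.integer(round(runif(1, r[1], r[2])))
  }, 1L)
  chrom <- sample(names(sizes), n_pub, replace = TRUE)
  strand <- sample(c("+", "-"), n_pub, replace = TRUE)

  # public transcripts are placed without overlap on either strand (one
  # combined lane per chromosome): only planted antisense loci overlap
  # another transcript, so unstranded ChIP signal at a gene reflects that
  # gene (plus any planted antisense partner), keeping planted coverage
  # regimes identifiable
  start <- integer(n_pub)
  for (cn in names(sizes)) {
    i <- which(chrom == cn)
    if (length(i)) {
      i <- sample(i)  # mix classes along the chromosome
      start[i] <- .place_lane(lens[i], lane_span, margin, config$min_gap)
    }
  }
  pub <- transcript_table(
    id = sprintf("%s_%04d", cls, seq_len(n_pub)),
    chrom = chrom, start = start, end = start + lens,
    strand = strand, rna_class = cls)

  # --- planted novel loci ----------------------------------------------
  novel <- list()
  occupied <- pub[, c("chrom", "start", "end", "strand")]
  if (config$n_novel_antisense > 0) {
    hosts_pool <- sample(which(pub$rna_class == "mRNA"))
    if (length(hosts_pool) < config$n_novel_antisense)
      stop("not enough mRNA hosts for requested antisense loci")
    pad <- config$min_gap  # keep clear of same-strand neighbours so
                           # coverage-merge assembly cannot bridge loci
    anti <- list()
    for (hi in hosts_pool) {
      if (length(anti) == config$n_novel_antisense) break
      h <- pub[hi, ]
      st <- if (h$strand == "+") "-" else "+"
      same <- occupied[occupied$strand == st &
                       occupied$chrom == h$chrom, , drop = FALSE]
      for (try in 1:30) {
        len <- as.integer(round(runif(1, 0.3, 0.8) * h$length))
        s <- h$start + sample.int(h$length - len, 1) - 1L
        if (!nrow(same) ||
            !any(same$start - pad < s + len & s - pad < same$end)) {
          anti[[length(anti) + 1]] <-
            data.frame(chrom = h$chrom, start = s, end = s + len,
                       strand = st, host = h$id)
          occupied <- rbind(occupied,
                            data.frame(chrom = h$chrom, start = s,
                                       end = s + len, strand = st))
          same <- rbind(same, data.frame(chrom = h$chrom, start = s,
                                         end = s + len, strand = st))
          break
        }
      }
    }
    if (length(anti) < config$n_novel_antisense)
      stop("placement failure for antisense novel loci: placed ",
           length(anti), " of ", config$n_novel_antisense)
    anti <- do.call(rbind, anti)
    anti$id <- sprintf("novel_AS_%03d", seq_len(nrow(anti)))
    anti$category <- "antisense"
    novel$antisense <- anti  # already appended to `occupied` above
  }
  if (config$n_novel_intergenic > 0) {
    inter <- list()
    for (i in seq_len(config$n_novel_intergenic)) {
      placed <- FALSE
      for (try in 1:500) {
        len <- as.integer(round(runif(1, config$novel_length_range[1],
                                      config$novel_length_range[2])))
        cn <- sample(names(sizes), 1)
        s <- sample.int(config$chrom_length - 2 * margin - len, 1) +
             margin - 1L
        here <- occupied[occupied$chrom == cn, , drop = FALSE]
        pad <- config$min_gap
        if (!nrow(here) ||
            !any(here$start - pad < s + len & s - pad < here$end)) {
          row <- data.frame(chrom = cn, start = s, end = s + len,
                            strand = sample(c("+", "-"), 1),
                            host = NA_character_)
          inter[[i]] <- row
          occupied <- rbind(occupied,
                            row[, c("chrom", "start", "end", "strand")])
          placed <- TRUE
          break
        }
      }
      if (!placed)
        stop("placement failure for intergenic novel locus after ",
             "500 retries")
    }
    inter <- do.call(rbind, inter)
    inter$id <- sprintf("novel_IG_%03d", seq_len(nrow(inter)))
    inter$category <- "intergenic"
    novel$intergenic <- inter  # already appended to `occupied` above
  }
  novel_df <- do.call(rbind, novel)
  if (is.null(novel_df))
    novel_df <- data.frame(chrom = character(), start = integer(),
                           end = integer(), strand = character(),
                           host = character(), id = character(),
                           category = character())
  novel_tx <- transcript_table(novel_df$id, novel_df$chrom, novel_df$start,
                               novel_df$end, novel_df$strand,
                               rep("novel", nrow(novel_df)))
  novel_tx$category <- novel_df$category
  novel_tx$host <- novel_df$host
  # plant the configured fraction exactly (the flagged set is random)
  novel_tx$cpg_planted <- logical(nrow(novel_tx))
  if (nrow(novel_tx) > 0)
    novel_tx$cpg_planted[sample.int(
      nrow(novel_tx), round(config$cpg_frac * nrow(novel_tx)))] <- TRUE

  # --- planted expression effects --------------------------------------
  all_ids <- c(pub$id, novel_tx$id)
  all_cls <- c(pub$rna_class, novel_tx$rna_class)
  lfc <- rnorm(length(all_ids), config$class_effect[all_cls],
               config$effect_sd)
  base <- vapply(all_cls, function(cl)
    .loguniform(1, config$class_base_mean[[cl]]), 1)

  # --- HIF targets ------------------------------------------------------
  last_chrom <- paste0("chr", config$n_chroms)
  cand <- which(all_cls %in% c("mRNA", "lncRNA") &
                lfc >= config$hif_target_min_lfc &
                c(pub$chrom, novel_tx$chrom) != last_chrom)
  n_tgt <- round(config$frac_hif_targets * length(cand))
  tgt <- sort(cand[sample.int(length(cand), n_tgt)])
  hif_label <- rep("none", length(all_ids))
  lab_pool <- c("HIF1", "HIF2", "both")
  hif_label[tgt] <- sample(lab_pool, n_tgt, replace = TRUE,
                           prob = c(config$hif1_frac, config$hif2_frac,
                                    1 - config$hif1_frac - config$hif2_frac))
  # HIF targets are strongly expressed; redraw baselines from the upper range
  base[tgt] <- .loguniform(n_tgt, c(300, 3000))
  pause_mode <- rep("normal", length(all_ids))
  pause_mode[tgt] <- "pause_release"
  # an exactly-rounded minority of targets recruit RNApol2 de novo
  n_dn <- round(config$frac_de_novo * n_tgt)
  if (n_dn > 0) pause_mode[tgt[sample.int(n_tgt, n_dn)]] <- "de_novo"

  effects <- data.frame(id = all_ids, rna_class = all_cls,
                        true_lfc = lfc, base_mean = base,
                        hif_label = hif_label, pause_mode = pause_mode,
                        is_novel = all_ids %in% novel_tx$id,
                        stringsAsFactors = FALSE)

  # --- peaks ------------------------------------------------------------
  all_tx <- rbind(pub[, c("id", "chrom", "start", "end", "strand",
                          "rna_class", "tss", "length")],
                  novel_tx[, c("id", "chrom", "start", "end", "strand",
                               "rna_class", "tss", "length")])
  half <- config$peak_width %/% 2L
  prox <- list()
  for (i in tgt) {
    lab <- hif_label[i]
    facs <- if (lab == "both") c("HIF1", "HIF2") else lab
    t_row <- all_tx[all_tx$id == all_ids[i], ]
    for (f in facs) {
      summit <- t_row$tss + as.integer(round(runif(1, -1500, 1500)))
      prox[[length(prox) + 1]] <-
        data.frame(chrom = t_row$chrom, start = summit - half,
                   end = summit + half, summit = summit, factor = f,
                   target_id = t_row$id, stringsAsFactors = FALSE)
    }
  }
  prox <- if (length(prox)) do.call(rbind, prox) else
    data.frame(chrom = character(), start = integer(), end = integer(),
               summit = integer(), factor = character(),
               target_id = character())
  distal <- list()
  peak_chroms <- setdiff(names(sizes), last_chrom)
  for (f in c("HIF1", "HIF2")) {
    n_prox_f <- sum(prox$factor == f)
    n_dist <- if (!is.null(config$n_distal_peaks))
      config$n_distal_peaks
    else {
      fr <- config$distal_frac[[f]]
      round(n_prox_f * fr / (1 - fr))
    }
    for (j in seq_len(n_dist)) {
      placed <- FALSE
      for (try in 1:1000) {
        cn <- sample(peak_chroms, 1)
        p <- sample.int(config$chrom_length - 2 * margin, 1) + margin - 1L
        tss_here <- all_tx$tss[all_tx$chrom == cn]
        if (!length(tss_here) || min(abs(tss_here - p)) > 3000) {
          distal[[length(distal) + 1]] <-
            data.frame(chrom = cn, start = p - half, end = p + half,
                       summit = p, factor = f, target_id = NA_character_,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
      }
      if (!placed) stop("could not place distal peak away from all TSSs")
    }
  }
  peaks <- rbind(prox, if (length(distal)) do.call(rbind, distal))
  peaks$strand <- "."
  peaks$id <- sprintf("%s_peak_%03d", peaks$factor,
                      stats::ave(seq_len(nrow(peaks)), peaks$factor,
                                 FUN = seq_along))
  peaks <- peaks[, c("id", "chrom", "start", "end", "strand", "summit",
                     "factor", "target_id")]

  list(annotation = pub,
       truth = list(effects = effects, novel = novel_tx, peaks = peaks,
                    pause_offset = config$pause_offset,
                    chrom_sizes = sizes))
}

#' Simulate the genome sequence
#'
#' Uniformly drawn A/C/G/T background with CpG suppression (80% of CpG
#' dinucleotides rewritten, G+C fraction 0.4) so that random background does
#' not qualify as a CpG island; a high-GC, high-CpG island sequence is
#' planted within 1000 bp upstream of the TSS of the configured fraction of
#' novel loci.
#'
#' @param config a [sim_config()].
#' @param sim optional result of [simulate_annotation()] (recomputed from
#'   `config` if missing).
#' @return named character vector of chromosome sequences.
#' @export
simulate_genome <- function(config, sim = NULL) {
  if (is.null(sim)) sim <- simulate_annotation(config)
  sizes <- .sim_chrom_sizes(config)
  set.seed(config$seed + 11L)
  genome <- lapply(sizes, function(L) {
    s <- sample(c("A", "C", "G", "T"), L, replace = TRUE,
                prob = c(0.3, 0.2, 0.2, 0.3))
    cg <- which(s[-L] == "C" & s[-1] == "G")
    if (length(cg)) {
      dep <- cg[runif(length(cg)) < 0.8]
      s[dep] <- "T"
    }
    s
  })
  novel <- sim$truth$novel
  plant <- which(novel$cpg_planted)
  il <- config$cpg_island_length
  for (i in plant) {
    isl <- sample(c("A", "C", "G", "T"), il, replace = TRUE,
                  prob = c(0.2, 0.3, 0.3, 0.2))
    at <- seq(1, il - 1, by = 8)
    isl[at] <- "C"
    isl[at + 1] <- "G"
    gap <- as.integer(round(runif(1, 50, 1000 - il - 50)))
    if (novel$strand[i] == "+") {
      s0 <- novel$tss[i] - gap - il          # 0-based island start
    } else {
      s0 <- novel$tss[i] + gap + 1L
    }
    s0 <- max(0L, min(s0, sizes[[novel$chrom[i]]] - il))
    genome[[novel$chrom[i]]][(s0 + 1):(s0 + il)] <- isl
  }
  vapply(genome, paste, "", collapse = "")
}

#' Write a genome as FASTA (70-column wrap)
#' @param genome named character vector of sequences.
#' @param path output path.
#' @export
write_genome_fasta <- function(genome, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(genome), path,
                              width = 70L)
  invisible(path)
}

#' Simulate the count matrix across conditions
#'
#' Counts are negative binomial with common dispersion around per-condition
#' means: normoxia at the planted baseline, hypoxia (and siControl) at
#' baseline x 2^log2FC. For HIF-dependent transcripts the planted log2
#' induction is attributed to the responsible factor(s) (split equally for
#' `both`); the matching siRNA retains only `(1 - knockdown_efficiency)` of
#' the attributed induction. HIF-independent induction is untouched by any
#' siRNA.
#'
#' @param config a [sim_config()].
#' @param annotation transcript table to generate counts for.
#' @param truth ground truth from [simulate_annotation()].
#' @return a [count_matrix()] with the six conditions (times
#'   `config$replicates`).
#' @export
simulate_counts <- function(config, annotation, truth) {
  set.seed(config$seed + 13L)
  eff <- truth$effects[match(annotation$id, truth$effects$id), ]
  if (anyNA(eff$id)) stop("annotation and ground truth are inconsistent")
  ke <- config$knockdown_efficiency
  # a transcript labelled `both` requires both factors, so either siRNA
  # alone removes the whole HIF-attributable induction (the MALAT1 pattern)
  dep1 <- eff$hif_label %in% c("HIF1", "both")
  dep2 <- eff$hif_label %in% c("HIF2", "both")
  lfc <- eff$true_lfc
  mu <- cbind(
    normoxia          = eff$base_mean,
    hypoxia           = eff$base_mean * 2^lfc,
    hypoxia_siHIF1a   = eff$base_mean * 2^(lfc - ke * lfc * dep1),
    hypoxia_siHIF2a   = eff$base_mean * 2^(lfc - ke * lfc * dep2),
    hypoxia_siBoth    = eff$base_mean * 2^(lfc - ke * lfc * (dep1 | dep2)),
    hypoxia_siControl = eff$base_mean * 2^lfc)
  reps <- config$replicates
  cols <- if (reps == 1) colnames(mu) else
    paste0(rep(colnames(mu), each = reps), "_rep",
           rep(seq_len(reps), times = ncol(mu)))
  mu <- mu[, rep(seq_len(ncol(mu)), each = reps), drop = FALSE]
  counts <- if (config$dispersion > 0)
    matrix(rnbinom(length(mu), mu = mu, size = 1 / config$dispersion),
           nrow = nrow(mu))
  else
    matrix(stats::rpois(length(mu), lambda = mu), nrow = nrow(mu))
  rownames(counts) <- annotation$id
  colnames(counts) <- cols
  count_matrix(counts)
}

# relative expression per condition; scaled so coverage amplitudes are
# well above the induction-mode classifier's 0.1 signal/bp pseudocount
.rel_expr <- function(eff, condition) {
  e <- eff$base_mean
  if (condition == "hypoxia") e <- e * 2^eff$true_lfc
  e / 100
}

#' Simulate a per-base coverage track
#'
#' Noise-free kernels: RNApol2 is a Gaussian pause peak centred (strand
#' aware) at `TSS + pause_offset` plus uniform gene-body signal. At
#' pause-release HIF targets the hypoxic body signal rises while the pause
#' peak stays at its normoxic height; at de novo recruitment targets both
#' start near zero in normoxia; at all other genes promoter and body scale
#' together with condition expression. H3K4me3 mirrors RNApol2 with a
#' broader, downstream-shifted kernel; DNase is a fixed promoter kernel
#' identical in both conditions. Mark `"RNAseq"` gives uniform stranded
#' transcript coverage proportional to condition expression (used by the
#' novel-transcript assembler).
#'
#' @param config a [sim_config()].
#' @param annotation public transcript table.
#' @param truth ground truth from [simulate_annotation()] (novel loci are
#'   transcribed too and contribute signal).
#' @param condition `"normoxia"` or `"hypoxia"`.
#' @param mark `"RNApol2"`, `"H3K4me3"`, `"DNase"` or `"RNAseq"`.
#' @param strand for `mark = "RNAseq"`: which strand's coverage.
#' @return a [coverage_track()].
#' @export
simulate_coverage <- function(config, annotation, truth,
                              condition = c("normoxia", "hypoxia"),
                              mark = c("RNApol2", "H3K4me3", "DNase",
                                       "RNAseq"),
                              strand = ".") {
  condition <- match.arg(condition)
  mark <- match.arg(mark)
  sizes <- truth$chrom_sizes
  tx <- rbind(annotation[, c("id", "chrom", "start", "end", "strand",
                             "tss", "length")],
              truth$novel[, c("id", "chrom", "start", "end", "strand",
                              "tss", "length")])
  eff <- truth$effects[match(tx$id, truth$effects$id), ]
  rel_n <- .rel_expr(eff, "normoxia")
  rel_c <- .rel_expr(eff, condition)

  values <- lapply(sizes, numeric)
  add <- function(cn, pos, v) {
    ok <- pos >= 1 & pos <= sizes[[cn]]
    values[[cn]][pos[ok]] <<- values[[cn]][pos[ok]] + v[ok]
  }

  if (mark == "RNAseq") {
    keep <- tx$strand == strand
    for (i in which(keep)) {
      pos <- (tx$start[i] + 1L):tx$end[i]
      add(tx$chrom[i], pos, rep(config$body_height * rel_c[i],
                                length(pos)))
    }
    return(coverage_track(values, mark, condition, strand))
  }

  off <- if (mark == "H3K4me3") config$pause_offset + 100 else
         config$pause_offset
  w <- if (mark == "H3K4me3") config$pause_width * 3 else config$pause_width
  if (mark == "DNase") { off <- 0; w <- 100 }
  kd <- seq(-ceiling(4 * w), ceiling(4 * w))
  kern <- exp(-(kd)^2 / (2 * w^2))

  for (i in seq_len(nrow(tx))) {
    mode <- eff$pause_mode[i]
    if (mark == "DNase") {
      amp_p <- 5 * rel_n[i]; amp_b <- 0
    } else if (mode == "pause_release") {
      amp_p <- config$pause_height * rel_n[i]
      amp_b <- config$body_height * rel_c[i]
    } else if (mode == "de_novo") {
      sc <- if (condition == "normoxia") 0.02 else 1
      amp_p <- config$pause_height * rel_c[i] * sc
      amp_b <- config$body_height * rel_c[i] * sc
    } else {
      amp_p <- config$pause_height * rel_c[i]
      amp_b <- config$body_height * rel_c[i]
    }
    dir <- if (tx$strand[i] == "+") 1L else -1L
    # gene body starts downstream of the pause region so promoter-window
    # signal reflects pausing only
    if (amp_b > 0 && tx$length[i] > config$body_start) {
      pos <- tx$tss[i] + dir * (config$body_start:(tx$length[i] - 1L)) + 1L
      add(tx$chrom[i], pos, rep(amp_b, length(pos)))
    }
    if (amp_p > 0) {
      pos <- tx$tss[i] + dir * (off + kd) + 1L
      add(tx$chrom[i], pos, amp_p * kern)
    }
  }
  coverage_track(values, mark, condition, ".")
}

#' Simulate a complete data set and write it to disk
#'
#' Writes genome FASTA, chrom sizes, public annotation (GTF), ground-truth
#' tables, HIF peak BEDs, the count matrix, per-mark/condition ChIP
#' bedGraphs and stranded RNA-seq bedGraphs under one output directory.
#'
#' @param config a [sim_config()].
#' @param outdir output directory (created if needed).
#' @return (invisibly) a list with all in-memory objects and file paths.
#' @export
simulate_dataset <- function(config, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  p <- function(...) file.path(outdir, ...)
  sim <- simulate_annotation(config)
  genome <- simulate_genome(config, sim)
  counts <- simulate_counts(config, sim$annotation, sim$truth)

  write_genome_fasta(genome, p("genome.fa"))
  write_chrom_sizes(sim$truth$chrom_sizes, p("chrom.sizes"))
  write_annotation(sim$annotation, p("annotation.gtf"))
  write_counts(counts, p("counts.tsv"))
  write_table(sim$truth$effects, p("truth_effects.tsv"))
  nov <- sim$truth$novel
  write_table(data.frame(id = nov$id, chrom = nov$chrom, start = nov$start,
                         end = nov$end, strand = nov$strand,
                         category = nov$category, host = nov$host,
                         cpg_planted = nov$cpg_planted),
              p("truth_novel.tsv"))
  write_table(sim$truth$peaks, p("truth_peaks.tsv"))
  for (f in c("HIF1", "HIF2"))
    write_peaks(sim$truth$peaks[sim$truth$peaks$factor == f, ],
                p(paste0("peaks_", tolower(f), ".bed")))

  tracks <- list()
  for (cond in c("normoxia", "hypoxia")) {
    for (mk in c("RNApol2", "H3K4me3", "DNase")) {
      tr <- simulate_coverage(config, sim$annotation, sim$truth, cond, mk)
      fn <- p(sprintf("%s_%s.bedgraph", tolower(mk), cond))
      write_coverage(tr, fn)
      tracks[[paste(mk, cond, sep = "_")]] <- fn
    }
    for (st in c("+", "-")) {
      tr <- simulate_coverage(config, sim$annotation, sim$truth, cond,
                              "RNAseq", strand = st)
      fn <- p(sprintf("rnaseq_%s_%s.bedgraph", cond,
                      if (st == "+") "plus" else "minus"))
      write_coverage(tr, fn)
      tracks[[paste("RNAseq", cond, st, sep = "_")]] <- fn
    }
  }
  invisible(list(config = config, sim = sim, genome = genome,
                 counts = counts, outdir = outdir, tracks = tracks))
}
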