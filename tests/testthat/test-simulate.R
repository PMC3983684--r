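cfg <- small_sim_config()
sim <- simulate_annotation(cfg)

test_that("simulation is byte-deterministic under a fixed seed", {
  sim2 <- simulate_annotation(cfg)
  expect_identical(sim, sim2)
  g1 <- simulate_genome(cfg, sim)
  g2 <- simulate_genome(cfg, sim)
  expect_identical(g1, g2)
  c1 <- simulate_counts(cfg, sim$annotation, sim$truth)
  c2 <- simulate_counts(cfg, sim$annotation, sim$truth)
  expect_identical(c1$counts, c2$counts)
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  simulate_dataset(cfg, d1)
  simulate_dataset(cfg, d2)
  for (f in list.files(d1))
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
})

test_that("planted novel loci have the guaranteed overlap structure", {
  nov <- sim$truth$novel
  expect_equal(sum(nov$category == "intergenic"), 5L)
  expect_equal(sum(nov$category == "antisense"), 3L)
  expect_false(any(nov$id %in% sim$annotation$id))
  pub <- sim$annotation
  for (i in which(nov$category == "intergenic")) {
    any_overlap <- FALSE
    for (j in seq_len(nrow(pub)))
      if (oracle_overlap(nov[i, ], pub[j, ], "any_strand"))
        any_overlap <- TRUE
    expect_false(any_overlap, label = nov$id[i])
  }
  for (i in which(nov$category == "antisense")) {
    hosts <- 0
    for (j in seq_len(nrow(pub)))
      if (pub$rna_class[j] == "mRNA" &&
          oracle_overlap(nov[i, ], pub[j, ], "opposite_strand"))
        hosts <- hosts + 1
    expect_gte(hosts, 1)
  }
})

test_that("every HIF-dependent transcript has a peak within 2.5 kb", {
  eff <- sim$truth$effects
  peaks <- sim$truth$peaks
  all_tx <- rbind(sim$annotation[, c("id", "chrom", "tss")],
                  sim$truth$novel[, c("id", "chrom", "tss")])
  dep <- eff$id[eff$hif_label != "none"]
  expect_gt(length(dep), 0)
  for (id in dep) {
    tx <- all_tx[all_tx$id == id, ]
    lab <- eff$hif_label[eff$id == id]
    for (f in if (lab == "both") c("HIF1", "HIF2") else lab) {
      pk <- peaks[peaks$factor == f & peaks$chrom == tx$chrom, ]
      expect_true(any(abs(pk$summit - tx$tss) <= 2500), label = id)
    }
  }
  # distal peaks are genuinely distal from every TSS
  for (j in which(is.na(peaks$target_id))) {
    tss <- all_tx$tss[all_tx$chrom == peaks$chrom[j]]
    expect_gt(min(abs(tss - peaks$summit[j])), 2500)
  }
})

test_that("class-wise median of planted log2FC tracks the class effect", {
  eff <- sim$truth$effects
  for (cl in names(cfg$class_counts)) {
    v <- eff$true_lfc[eff$rna_class == cl & eff$hif_label == "none"]
    # 3x the large-sample SE of a normal median, 1.2533 sd/sqrt(n)
    tol <- 3 * 1.2533 * cfg$effect_sd / sqrt(length(v))
    expect_lt(abs(median(v) - cfg$class_effect[[cl]]), tol)
  }
})

test_that("counts converge to the planted fold-change at low dispersion", {
  ann <- transcript_table(sprintf("t%03d", 1:200), "chr1",
                          seq(0, by = 1500, length.out = 200),
                          seq(0, by = 1500, length.out = 200) + 1000,
                          "+", "mRNA")
  truth <- list(effects = data.frame(
    id = ann$id, rna_class = "mRNA", true_lfc = 1, base_mean = 1e5,
    hif_label = "none", pause_mode = "normal", is_novel = FALSE))
  c0 <- sim_config(seed = 2, dispersion = 1e-6)
  cm <- simulate_counts(c0, ann, truth)
  ratio <- cm$counts[, "hypoxia"] / cm$counts[, "normoxia"]
  expect_lt(max(abs(ratio - 2)), 0.1)  # 5% on each draw at mu = 1e5
  expect_lt(abs(mean(ratio) - 2), 0.02)
})

test_that("complete knockdown abolishes induction for both-dependent genes", {
  ann <- transcript_table("t1", "chr1", 0, 1000, "+", "mRNA")
  truth <- list(effects = data.frame(
    id = "t1", rna_class = "mRNA", true_lfc = 2, base_mean = 1e5,
    hif_label = "both", pause_mode = "pause_release", is_novel = FALSE))
  c0 <- sim_config(seed = 3, dispersion = 1e-6, knockdown_efficiency = 1)
  cm <- simulate_counts(c0, ann, truth)
  expect_lt(abs(cm$counts[, "hypoxia_siBoth"] /
                cm$counts[, "normoxia"] - 1), 0.05)
  expect_lt(abs(cm$counts[, "hypoxia_siHIF1a"] /
                cm$counts[, "normoxia"] - 1), 0.05)
  expect_gt(cm$counts[, "hypoxia"] / cm$counts[, "normoxia"], 3.5)
})

test_that("coverage kernels encode the planted pausing regimes", {
  dn_n <- simulate_coverage(cfg, sim$annotation, sim$truth, "normoxia",
                            "DNase")
  dn_h <- simulate_coverage(cfg, sim$annotation, sim$truth, "hypoxia",
                            "DNase")
  expect_identical(dn_n$values, dn_h$values)

  pol_n <- simulate_coverage(cfg, sim$annotation, sim$truth, "normoxia",
                             "RNApol2")
  pol_h <- simulate_coverage(cfg, sim$annotation, sim$truth, "hypoxia",
                             "RNApol2")
  eff <- sim$truth$effects
  pr <- eff$id[eff$pause_mode == "pause_release"]
  # overlapping antisense loci convolve into the unstranded signal, so
  # check the clean (non-host) pause-release genes
  pr <- setdiff(pr, sim$truth$novel$host)
  expect_gt(length(pr), 0)
  for (id in pr) {
    tx <- sim$annotation[sim$annotation$id == id, ]
    dir <- if (tx$strand == "+") 1L else -1L
    # noise-free argmax sits at TSS + pause_offset
    win <- tx$tss + dir * (0:150) + 1L
    vn <- pol_n$values[[tx$chrom]]
    vh <- pol_h$values[[tx$chrom]]
    expect_equal(win[which.max(vn[win])], tx$tss + dir * 42 + 1L)
    # pause summit equal across conditions, body strictly higher in hypoxia
    s_pos <- tx$tss + dir * 42 + 1L
    expect_equal(vn[s_pos], vh[s_pos], tolerance = 1e-12)
    body <- tx$tss + dir * (400:(tx$length - 1)) + 1L
    expect_gt(mean(vh[body]), mean(vn[body]))
  }
})

test_that("CpG islands are planted only when requested", {
  cfg0 <- small_sim_config(cpg_frac = 0)
  sim0 <- simulate_annotation(cfg0)
  expect_false(any(sim0$truth$novel$cpg_planted))
  g0 <- simulate_genome(cfg0, sim0)
  isl <- find_cpg_islands(g0)
  expect_equal(nrow(isl), 0L)  # depleted background yields no islands
})
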