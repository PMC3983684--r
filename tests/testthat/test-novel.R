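test_that("assembly merges blocks across small gaps only", {
  v <- numeric(2000)
  v[301:500] <- 2     # 0-based [300, 500)
  v[551:800] <- 2     # 50-bp gap
  trk <- list("+" = coverage_track(list(chr1 = v), "RNAseq", "x", "+"))
  empty_ann <- toy_annotation()[0, ]
  one <- assemble_unexplained(trk, empty_ann, min_depth = 1,
                              max_gap = 100, min_length = 200)
  expect_equal(nrow(one), 1L)
  expect_equal(c(one$start, one$end), c(300L, 800L))
  two <- assemble_unexplained(trk, empty_ann, min_depth = 1,
                              max_gap = 20, min_length = 200)
  expect_equal(nrow(two), 2L)
  expect_equal(two$tss, two$start)  # '+' strand: 5'-most covered base
  # same-strand annotation explains the first block away
  ann <- transcript_table("t1", "chr1", 250, 520, "+", "mRNA")
  left <- assemble_unexplained(trk, ann, min_depth = 1, max_gap = 20,
                               min_length = 200)
  expect_equal(nrow(left), 1L)
  expect_equal(left$start, 550L)
})

test_that("candidates are split into intergenic and antisense", {
  ann <- transcript_table("host", "chr1", 1000, 5000, "-", "mRNA")
  cand <- data.frame(id = c("c1", "c2", "c3"), chrom = "chr1",
                     start = c(2000, 8000, 1500),
                     end = c(2600, 8600, 2100),
                     strand = c("+", "+", "-"),
                     stringsAsFactors = FALSE)
  out <- classify_novel(cand, ann)
  expect_equal(out$category[out$id == "c1"], "antisense")
  expect_equal(out$overlapping_sense_id[out$id == "c1"], "host")
  expect_equal(out$category[out$id == "c2"], "intergenic")
  expect_false("c3" %in% out$id)  # same-strand overlap: not novel
})

test_that("CpG island finder applies all three composition thresholds", {
  isl <- find_cpg_islands(c(chr = strrep("CG", 150)))
  expect_equal(nrow(isl), 1L)
  expect_equal(isl$gc_fraction, 1)
  expect_gte(isl$obs_exp_cpg, 1)
  expect_equal(nrow(find_cpg_islands(c(chr = strrep("AT", 150)))), 0L)
  expect_equal(nrow(find_cpg_islands(c(chr = strrep("N", 300)))), 0L)
  # islands never overlap each other and re-pass their own thresholds
  set.seed(31)
  bg <- paste(sample(c("A", "T", "C", "G"), 5000, TRUE,
                     prob = c(.35, .35, .15, .15)), collapse = "")
  seqs <- c(chr = paste0(substr(bg, 1, 2000), strrep("CG", 200),
                         substr(bg, 2001, 5000)))
  isl <- find_cpg_islands(seqs)
  expect_gte(nrow(isl), 1L)
  if (nrow(isl) > 1) {
    o <- order(isl$start)
    expect_true(all(isl$start[o][-1] >= isl$end[o][-nrow(isl)]))
  }
  expect_true(all(isl$gc_fraction >= 0.5 & isl$obs_exp_cpg >= 0.6 &
                  isl$length >= 200))
})

test_that("promoter CpG flag uses an inclusive 1-kb window", {
  novel <- data.frame(chrom = "chr1", tss = c(5000L, 5000L))
  near <- data.frame(chrom = "chr1", start = 3800L, end = 4002L)
  far <- data.frame(chrom = "chr1", start = 3700L, end = 3999L)
  expect_true(promoter_cpg_flag(novel[1, ], near))   # ends 999 bp away
  expect_false(promoter_cpg_flag(novel[1, ], far))   # ends 1001 bp away
  inside <- data.frame(chrom = "chr1", start = 4900L, end = 5100L)
  expect_true(promoter_cpg_flag(novel[1, ], inside))
})

test_that("coding potential equals the brute-force ORF scan", {
  orf <- paste0("ATG", strrep("GCA", 30), "TAA")  # one ORF end to end
  expect_equal(coding_potential(orf), 1)
  expect_equal(coding_potential(strrep("CCA", 40)), 0)  # no ATG
  expect_error(coding_potential("ATGTAA"), "60")
  set.seed(32)
  for (k in 1:200) {
    s <- paste(sample(c("A", "C", "G", "T"), sample(90:400, 1), TRUE),
               collapse = "")
    expect_equal(coding_potential(s), oracle_orf_score(s), label = s)
  }
  # stop-saturated random sequence scores low
  set.seed(33)
  littered <- paste(replicate(40, paste0(
    paste(sample(c("A", "C", "G", "T"), 15, TRUE), collapse = ""),
    "TAATAGTGA")), collapse = "")
  expect_lt(coding_potential(littered), 0.3)
})

test_that("sense/antisense pairing distinguishes co- and counter-regulation", {
  expect_equal(pair_regulation(2, 1), "co_regulated")
  expect_equal(pair_regulation(2, -1), "counter_regulated")
  expect_equal(pair_regulation(2, 0.1), "unclassified")
  expect_equal(pair_regulation(c(-2, 0.2), c(-1, 3)),
               c("co_regulated", "unclassified"))
})

test_that("planted novel loci are recovered end-to-end with exact categories", {
  cfg <- small_sim_config(seed = 12L)
  sim <- simulate_annotation(cfg)
  trk <- list()
  for (st in c("+", "-")) {
    n <- simulate_coverage(cfg, sim$annotation, sim$truth, "normoxia",
                           "RNAseq", strand = st)
    h <- simulate_coverage(cfg, sim$annotation, sim$truth, "hypoxia",
                           "RNAseq", strand = st)
    trk[[st]] <- coverage_track(mapply(`+`, n$values, h$values,
                                       SIMPLIFY = FALSE),
                                "RNAseq", "pooled", st)
  }
  cand <- assemble_unexplained(trk, sim$annotation, min_depth = 0.02,
                               max_gap = 100, min_length = 200)
  out <- classify_novel(cand, sim$annotation)
  truth <- sim$truth$novel
  expect_equal(nrow(out), nrow(truth))
  expect_equal(sum(out$category == "intergenic"),
               sum(truth$category == "intergenic"))
  expect_equal(sum(out$category == "antisense"),
               sum(truth$category == "antisense"))
  for (i in seq_len(nrow(truth))) {
    match_i <- which(out$chrom == truth$chrom[i] &
                     out$strand == truth$strand[i] &
                     pmin(out$end, truth$end[i]) -
                       pmax(out$start, truth$start[i]) >=
                       0.9 * pmax(out$end - out$start, truth$length[i]))
    expect_equal(length(match_i), 1L, label = truth$id[i])
    expect_equal(out$category[match_i], truth$category[i])
  }
})
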