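test_that("top-induced selection is a prefix of the ranking", {
  expr <- data.frame(id = sprintf("t%02d", 1:10), rna_class = "mRNA",
                     lfc_hypoxia = 10:1 / 2, mean_cpm = 1)
  expect_equal(select_top_induced(expr, 1), "t01")
  expect_equal(select_top_induced(expr, 10), rank_by_induction(expr)$id)
  expect_equal(select_top_induced(expr, 4),
               rank_by_induction(expr)$id[1:4])
  expect_error(select_top_induced(expr, 11), "available")
})

genes2 <- transcript_table(c("gp", "gm"), "chr1", c(4000, 4000),
                           c(7000, 7000), c("+", "-"),
                           c("mRNA", "mRNA"))

test_that("metagene profiles are flat on constant tracks and linear raw", {
  trk <- flat_track(3)
  prof <- metagene(trk, genes2, window = c(-500, 500), bin_size = 10)
  expect_equal(length(prof$value), 100)
  expect_true(all(abs(prof$value - prof$value[1]) < 1e-12))
  raw1 <- metagene(trk, genes2, window = c(-500, 500), normalize = FALSE)
  expect_equal(raw1$value, rep(3, 100))
  trk2 <- flat_track(5)
  both <- coverage_track(list(chr1 = trk$values$chr1 + trk2$values$chr1),
                         "RNApol2", "normoxia")
  raw_sum <- metagene(both, genes2, window = c(-500, 500),
                      normalize = FALSE)
  raw2 <- metagene(trk2, genes2, window = c(-500, 500), normalize = FALSE)
  expect_equal(raw_sum$value, raw1$value + raw2$value)
  expect_error(metagene(trk, genes2[0, ]), "empty")
})

test_that("minus-strand windows mirror the plus-strand fixture", {
  v <- numeric(10000)
  v[4000 + 1 + 0:99] <- 7  # 100 bp of signal starting at each TSS
  v[6900 + 1 + 0:99] <- 7  # mirrored for the '-' gene (TSS at 6999)
  trk <- coverage_track(list(chr1 = v), "RNApol2", "normoxia")
  pp <- metagene(trk, genes2[1, ], window = c(-200, 200),
                 normalize = FALSE)
  pm <- metagene(trk, genes2[2, ], window = c(-200, 200),
                 normalize = FALSE)
  expect_equal(pm$value, pp$value)
  expect_true(all(pp$value[pp$bin_centre < 0] == 0))
})

test_that("pause summit offset reports the max bin centre", {
  prof <- data.frame(bin_centre = seq(-195, 195, by = 10),
                     value = 0)
  prof$value[prof$bin_centre == 105] <- 2
  class(prof) <- c("metagene_profile", "data.frame")
  expect_equal(pause_summit_offset(prof), 105)
  prof$value <- 1
  expect_error(pause_summit_offset(prof), "flat")
  prof$value[prof$bin_centre %in% c(-45, 105)] <- 5  # tied maxima
  expect_equal(pause_summit_offset(prof), -45)       # smaller |offset|
})

test_that("travelling ratio follows densities and is scale invariant", {
  tx <- transcript_table("g", "chr1", 2000, 5000, "+", "mRNA")
  uni <- travelling_ratio(flat_track(4), tx)
  expect_equal(uni$tr, 1)
  v <- numeric(10000)
  v[(2000 - 30 + 1):(2000 + 300)] <- 10
  v[(2000 + 300 + 1):5000] <- 2
  trk <- coverage_track(list(chr1 = v), "RNApol2", "normoxia")
  expect_equal(travelling_ratio(trk, tx)$tr, 5)
  scaled <- coverage_track(list(chr1 = v * 7), "RNApol2", "normoxia")
  expect_equal(travelling_ratio(scaled, tx)$tr, 5)
  short <- transcript_table("s", "chr1", 100, 400, "+", "mRNA")
  expect_warning(travelling_ratio(flat_track(1), short), "skipped")
})

test_that("rank-sum statistic matches exact enumeration for small n", {
  set.seed(51)
  for (k in 1:30) {
    x <- sample(1:1000, sample(3:8, 1))
    y <- sample(2000:3000, sample(3:8, 1)) / 1000
    got <- rank_sum_test(x, y)
    expect_equal(got$w, oracle_u_stat(x, y))
  }
  # p-value close to the exact permutation p away from the extremes
  for (k in 1:10) {
    x <- rnorm(6); y <- rnorm(6) + 0.5
    got <- rank_sum_test(x, y)
    exact <- oracle_ranksum_exact_p(x, y)
    if (exact > 0.05 && exact < 0.95)
      expect_lt(abs(got$p_value - exact), 0.08)
  }
})

test_that("identical travelling ratios give a null group shift", {
  ids <- sprintf("g%02d", 1:20)
  tr <- data.frame(id = ids, promoter_density = 5, body_density = 1,
                   tr = runif(20, 1, 6), undefined = FALSE,
                   condition = "normoxia")
  groups <- list(a = ids[1:10], b = ids[11:20])
  res <- tr_shift(tr, tr, groups)
  expect_equal(res$per_group$median_dlogTR, c(0, 0))
  expect_gt(res$p_value, 0.9)
  expect_error(tr_shift(tr, tr, list(a = ids[1:3], b = ids[4:20])),
               "minimum size")
})

test_that("induction modes follow the body/promoter fold rules", {
  mk <- function(p, b, cond) data.frame(
    id = "g", promoter_density = p, body_density = b, tr = p / b,
    undefined = FALSE, condition = cond)
  pr <- classify_induction_mode(mk(10, 1, "n"), mk(10, 4, "h"))
  expect_equal(pr$mode, "pause_release")
  dn <- classify_induction_mode(mk(0.1, 0.1, "n"), mk(5, 3, "h"))
  expect_equal(dn$mode, "de_novo_recruitment")
  un <- classify_induction_mode(mk(10, 1, "n"), mk(10, 1.5, "h"))
  expect_equal(un$mode, "unchanged")
  # intermediate promoter behaviour (between 1.5x and 2x) stays unchanged
  mid <- classify_induction_mode(mk(10, 1, "n"), mk(17, 4, "h"))
  expect_equal(mid$mode, "unchanged")
})
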