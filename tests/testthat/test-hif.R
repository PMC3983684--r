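mk_peaks <- function(chrom, summit, factor = "HIF1") {
  data.frame(id = sprintf("p%02d", seq_along(summit)), chrom = chrom,
             start = summit - 50L, end = summit + 50L, strand = ".",
             summit = summit, factor = factor, stringsAsFactors = FALSE)
}

test_that("peaks map to the nearest TSS with abundance tie-breaking", {
  tx <- transcript_table(c("near", "far"), "chr1", c(900, 1500),
                         c(1400, 2200), "+", "mRNA")
  got <- nearest_expressed_promoter(mk_peaks("chr1", 1000L), tx)
  expect_equal(got$transcript_id, "near")
  expect_equal(got$abs_distance, 100)
  expect_equal(got$distance, 100)  # summit downstream of the TSS
  tie <- transcript_table(c("lo", "hi"), "chr1", c(900, 1100),
                          c(1050, 1400), "+", "mRNA")
  got <- nearest_expressed_promoter(mk_peaks("chr1", 1000L), tie,
                                    abundance = c(lo = 5, hi = 50))
  expect_equal(got$transcript_id, "hi")
  expect_error(nearest_expressed_promoter(mk_peaks("chr1", 1L), tx[0, ]),
               "empty")
})

test_that("signed distance is negative upstream in transcript orientation", {
  minus <- transcript_table("m", "chr1", 1000, 2000, "-", "mRNA")
  got <- nearest_expressed_promoter(mk_peaks("chr1", 2100L), minus)
  expect_equal(got$distance, -101)  # beyond the 5' end on the '-' strand
})

test_that("nearest-promoter assignment equals the all-pairs oracle", {
  set.seed(41)
  tx <- transcript_table(sprintf("t%03d", 1:300),
                         sample(c("chr1", "chr2"), 300, TRUE),
                         s <- sample.int(99000, 300), s + 500,
                         sample(c("+", "-"), 300, TRUE), "mRNA")
  ab <- setNames(runif(300), tx$id)
  peaks <- mk_peaks(sample(c("chr1", "chr2"), 200, TRUE),
                    sample.int(100000, 200))
  got <- nearest_expressed_promoter(peaks, tx, ab)
  want <- oracle_nearest(peaks, tx, ab)
  expect_equal(got$transcript_id, want$transcript_id)
  expect_equal(got$abs_distance, want$abs_distance)
})

test_that("distance summaries report the distal fraction", {
  a <- data.frame(peak_id = sprintf("p%d", 1:4), factor = "HIF1",
                  transcript_id = "t", rna_class = "mRNA",
                  distance = c(1000, 3000, 5000, 2000),
                  abs_distance = c(1000, 3000, 5000, 2000))
  ds <- distance_summary(a)
  expect_equal(ds$HIF1$fraction_distal, 0.5)
  expect_equal(sum(ds$HIF1$histogram$count), 4)
  a$abs_distance <- 0
  expect_equal(distance_summary(a)$HIF1$fraction_distal, 0)
})

test_that("class shares sum to one and ignore row order", {
  a <- data.frame(peak_id = sprintf("p%d", 1:4), factor = "HIF2",
                  transcript_id = "t",
                  rna_class = c("mRNA", "mRNA", "mRNA", "lncRNA"),
                  distance = 0, abs_distance = 0)
  cp <- class_proportions(a)
  expect_equal(sort(cp$share), c(0.25, 0.75))
  expect_equal(sum(cp$share), 1)
  cp2 <- class_proportions(a[c(3, 1, 4, 2), ])
  expect_equal(cp2[order(cp2$rna_class), ], cp[order(cp$rna_class), ],
               ignore_attr = TRUE)
  one <- class_proportions(a[1, ])
  expect_equal(one$share, 1)
})

ranked4 <- data.frame(id = c("g1", "g2", "g3", "g4"),
                      lfc_hypoxia = c(4, 3, 2, 1))

test_that("enrichment score hits +/-1 for singleton extremes", {
  top <- gsea(ranked4, "g1", weight_p = 1, n_perm = 50, seed = 1)
  expect_equal(top$es, 1)
  expect_equal(top$leading_edge, "g1")
  bottom <- gsea(ranked4, "g4", weight_p = 1, n_perm = 50, seed = 1)
  expect_equal(bottom$es, -1)
  bottom0 <- gsea(ranked4, "g4", weight_p = 0, n_perm = 50, seed = 1)
  expect_equal(bottom0$es, -1)
  expect_error(gsea(ranked4, character(0)), "proper subset")
  expect_error(gsea(ranked4, ranked4$id), "proper subset")
})

test_that("permutation p-values are deterministic under a fixed seed", {
  r1 <- gsea(ranked4, c("g1", "g2"), n_perm = 200, seed = 9)
  r2 <- gsea(ranked4, c("g1", "g2"), n_perm = 200, seed = 9)
  expect_identical(r1$p_value, r2$p_value)
  expect_gt(r1$p_value, 0)
  expect_lte(r1$p_value, 1)
})

test_that("reversing the ranking negates the enrichment score", {
  set.seed(43)
  n <- 40
  ranked <- data.frame(id = sprintf("g%02d", 1:n),
                       lfc_hypoxia = sort(rnorm(n), decreasing = TRUE))
  revd <- ranked[n:1, ]
  for (k in 1:10) {
    set <- sample(ranked$id, 6)
    fwd <- gsea(ranked, set, weight_p = 0, n_perm = 2, seed = 1)$es
    bwd <- gsea(revd, set, weight_p = 0, n_perm = 2, seed = 1)$es
    expect_equal(bwd, -fwd, tolerance = 1e-12)
    # weighted case against the loop-based oracle
    expect_equal(gsea(ranked, set, weight_p = 1, n_perm = 2,
                      seed = 1)$es,
                 oracle_gsea_es(ranked$id, ranked$lfc_hypoxia, set, 1),
                 tolerance = 1e-12)
  }
})
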