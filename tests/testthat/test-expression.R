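test_that("CPM normalization is exact and scale invariant", {
  m <- matrix(c(100, 999900, 50, 999950), ncol = 2,
              dimnames = list(c("a", "b"), c("s1", "s2")))
  cpm <- normalize_cpm(count_matrix(m))
  expect_equal(cpm["a", "s1"], 100)
  doubled <- normalize_cpm(count_matrix(m * 2))
  expect_equal(doubled, cpm)
  zero <- matrix(0, 1, 1, dimnames = list("a", "s1"))
  expect_error(normalize_cpm(count_matrix(zero)), "zero library")
})

test_that("log2 fold-change handles zeros and is antisymmetric", {
  expect_equal(log2_fold_change(5, 5), 0)
  expect_equal(log2_fold_change(0, 0), 0)
  expect_equal(log2_fold_change(7.5, 31.5, 0.5), 2)
  expect_error(log2_fold_change(1, 2, pseudocount = 0), "pseudocount")
  set.seed(21)
  a <- runif(200, 0, 50); b <- runif(200, 0, 50)
  expect_equal(log2_fold_change(a, b), -log2_fold_change(b, a))
})

test_that("class summaries use interpolated quartiles and ignore row order", {
  expr <- data.frame(id = c("a", "b", "c", "d"),
                     rna_class = c("mRNA", "mRNA", "mRNA", "snRNA"),
                     lfc_hypoxia = c(-1, 0, 1, 0.5))
  s <- summarize_by_class(expr)
  m <- s[s$rna_class == "mRNA", ]
  expect_equal(unlist(m[c("min", "q1", "median", "q3", "max")]),
               c(min = -1, q1 = -0.5, median = 0, q3 = 0.5, max = 1))
  single <- s[s$rna_class == "snRNA", ]
  expect_true(all(single[c("min", "q1", "median", "q3", "max")] == 0.5))
  perm <- summarize_by_class(expr[c(3, 1, 4, 2), ])
  expect_equal(perm, s)
  expect_true(all(s$min <= s$q1 & s$q1 <= s$median &
                  s$median <= s$q3 & s$q3 <= s$max))
})

test_that("induction ranking is deterministic with documented tie rules", {
  expr <- data.frame(id = c("A", "B", "C"),
                     rna_class = "mRNA",
                     lfc_hypoxia = c(2, -1, 0),
                     mean_cpm = c(1, 1, 1))
  expect_equal(rank_by_induction(expr)$id, c("A", "C", "B"))
  tie <- data.frame(id = c("lo", "hi"), rna_class = "mRNA",
                    lfc_hypoxia = c(1, 1), mean_cpm = c(10, 50))
  expect_equal(rank_by_induction(tie)$id, c("hi", "lo"))
  set.seed(22)
  uniq <- data.frame(id = sprintf("t%02d", 1:20), rna_class = "mRNA",
                     lfc_hypoxia = sample(seq(-2, 2, length.out = 20)),
                     mean_cpm = runif(20))
  fwd <- rank_by_induction(uniq)$id
  rev_ <- uniq
  rev_$lfc_hypoxia <- -rev_$lfc_hypoxia
  expect_equal(rank_by_induction(rev_)$id, rev(fwd))
})

test_that("siRNA dependence calls follow the delta rule", {
  expr <- data.frame(id = c("h1", "both", "none"), rna_class = "lncRNA",
                     lfc_hypoxia = c(2, 2, 2),
                     lfc_siHIF1a = c(-1.2, -1.5, -0.1),
                     lfc_siHIF2a = c(-0.1, -1.1, 0.2),
                     lfc_siBoth = c(-1.4, -1.6, -0.2))
  sm <- sirna_matrix(expr, expr$id)
  expect_equal(sm$hif_call, c("HIF1", "both", "none"))
  expect_error(sirna_matrix(expr[, -4], expr$id), "siHIF1a")
})

test_that("platform concordance equals a first-principles Spearman rho", {
  x <- setNames(1:10, letters[1:10])
  expect_equal(platform_concordance(x, x * 2), 1)
  expect_equal(platform_concordance(x, -x), -1)
  expect_error(platform_concordance(x[1:2], x[1:2]), "at least 3")
  set.seed(23)
  for (k in 1:5) {
    v <- setNames(sample(1:8, 200, replace = TRUE) + runif(200),
                  sprintf("t%03d", 1:200))
    w <- setNames(sample(1:8, 200, replace = TRUE) + runif(200),
                  sprintf("t%03d", 1:200))
    expect_equal(platform_concordance(v, w), oracle_spearman(v, w),
                 tolerance = 1e-12)
  }
})
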