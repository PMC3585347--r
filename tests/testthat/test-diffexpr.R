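test_that("ac_probability matches its closed form and normalizes", {
  expect_equal(ac_probability(0, 0, 1e6, 1e6), 0.5)
  # full normalization over y for a fixed x
  k <- 0:1e4
  expect_gte(sum(ac_probability(k, 5, 1e6, 1e6)), 1 - 1e-12)
  # finite deep into library-scale counts
  expect_true(is.finite(ac_probability(1e6, 1e6, 3e6, 3e6)))
  expect_error(ac_probability(-1, 0, 1, 1), "counts")
})

test_that("ac_probability agrees with independent negative-binomial route", {
  # the pmf equals dnbinom(y, x+1, n1/(n1+n2)); an independent
  # derivation from the same model, computed by different code
  grid <- expand.grid(x = c(0, 1, 7, 30, 100), y = c(0, 2, 25, 90),
                      r = c(0.5, 1, 2))
  p_pkg <- ac_probability(grid$y, grid$x, 1e6, 1e6 * grid$r)
  p_nb <- dnbinom(grid$y, grid$x + 1, 1 / (1 + grid$r))
  expect_equal(p_pkg, p_nb, tolerance = 1e-12)
})

test_that("ac_pvalue matches the tail-sum oracle and is symmetric", {
  # absolute comparison: the oracle's complementary tail loses relative
  # precision below ~1e-15 where both values are numerically zero
  for (r in c(0.5, 1, 2)) {
    for (x in c(0, 3, 10, 40)) {
      for (y in c(0, 1, 12, 60)) {
        expect_lt(abs(ac_pvalue(x, y, 1e6, 1e6 * r) -
                        oracle_ac_pvalue(x, y, 1e6, 1e6 * r)), 1e-12)
      }
    }
  }
  # equal counts in equal libraries can never look differential
  expect_equal(ac_pvalue(10, 10, 1e6, 1e6), 1)
  # strong difference: doubled lower tail, far below 0.05
  p <- ac_pvalue(100, 0, 1e6, 1e6)
  expect_equal(p, oracle_ac_pvalue(100, 0, 1e6, 1e6))
  expect_lt(p, 1e-20)
  # library-swap behavior: the doubled-tail construction is symmetric
  # up to discreteness; the difference is bounded by the point masses
  # at the observed counts, and vanishes at the balanced point
  expect_equal(ac_pvalue(10, 10, 1e6, 1e6), ac_pvalue(10, 10, 1e6, 1e6))
  set.seed(1)
  for (i in 1:50) {
    x <- sample(0:200, 1); y <- sample(0:200, 1)
    n1 <- sample(1e5:1e6, 1); n2 <- sample(1e5:1e6, 1)
    gap <- abs(ac_pvalue(x, y, n1, n2) - ac_pvalue(y, x, n2, n1))
    bound <- 2 * (ac_probability(y, x, n1, n2) +
                    ac_probability(x, y, n2, n1))
    expect_lte(gap, bound + 1e-12)
  }
})

test_that("upper tail decreases in y beyond the mode", {
  x <- 50
  y <- 60:120
  # P(Y >= y) via the oracle pmf: strictly decreasing beyond the mode
  pmf <- oracle_ac_pmf(x, 1e6, 1e6, max(y))
  upper <- 1 - c(0, cumsum(pmf))[y]
  expect_true(all(diff(upper) < 0))
  # and the two-sided p-value is non-increasing there as well
  p <- ac_pvalue(rep(x, length(y)), y, 1e6, 1e6)
  expect_true(all(diff(p) <= 1e-15))
})

test_that("bh_fdr reproduces the literal step-up and its invariances", {
  expect_identical(bh_fdr(numeric(0)), numeric(0))
  expect_equal(bh_fdr(0.01), 0.01)
  expect_equal(bh_fdr(rep(1, 5)), rep(1, 5))
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)),
               oracle_bh(c(0.01, 0.02, 0.03, 0.04)))
  set.seed(7)
  p <- runif(500)
  expect_equal(bh_fdr(p), oracle_bh(p), tolerance = 1e-12)
  # adjusting commutes with reordering
  ord <- sample(length(p))
  expect_equal(bh_fdr(p[ord]), bh_fdr(p)[ord], tolerance = 1e-12)
  expect_error(bh_fdr(c(0.5, 1.2)), "0, 1")
})

test_that("call_differential applies the combined filter and cutoffs", {
  counts_a <- c(g_low = 150, g_eq = 100, g_up = 50, g_down = 400)
  counts_b <- c(g_low = 40, g_eq = 100, g_up = 250, g_down = 100)
  de <- call_differential(make_records(counts_a, 1e6),
                          make_records(counts_b, 1e6))
  # combined 190 excluded before testing
  expect_false("g_low" %in% de$gene_id)
  expect_identical(nrow(de), 3L)
  eq <- de[de$gene_id == "g_eq", ]
  expect_equal(eq$log2_ratio, 0)
  expect_false(eq$significant)
  expect_identical(de$direction[de$gene_id == "g_up"], "up")
  expect_identical(de$direction[de$gene_id == "g_down"], "down")
  expect_true(all(de$fdr >= 0 & de$fdr <= 1))
})

test_that("zero counts report large but capped folds", {
  counts_a <- c(gA = 500, gB = 1000)
  counts_b <- c(gA = 0, gB = 1000)
  de <- call_differential(make_records(counts_a, 1e6),
                          make_records(counts_b, 1e6))
  expect_lte(abs(de$log2_ratio[de$gene_id == "gA"]), log2(1e4))
  expect_identical(de$direction[de$gene_id == "gA"], "down")
})

test_that("fold bins are cumulative with closed thresholds", {
  counts_a <- c(g2 = 100, g5 = 100, g1 = 100)
  counts_b <- c(g2 = 200, g5 = 500, g1 = 100)
  de <- call_differential(make_records(counts_a, 1e6),
                          make_records(counts_b, 1e6))
  bins <- fold_change_bins(de)
  # fold exactly 2 sits in >=1.5 and >=2, not >=5
  expect_equal(bins$up[bins$threshold == 1.5], 2)
  expect_equal(bins$up[bins$threshold == 2], 2)
  expect_equal(bins$up[bins$threshold == 5], 1)
  expect_equal(sum(bins$down), 0)
  # empty input gives zero bins everywhere
  empty <- fold_change_bins(de[de$significant & de$gene_id == "none", ])
  expect_true(all(empty$up == 0) && all(empty$down == 0))
  expect_error(fold_change_bins(de, thresholds = c(2, 1.5)), "ascending")
})

test_that("a pair of identical libraries yields no calls", {
  counts <- setNames(round(seq(100, 5000, length.out = 30)),
                     paste0("g", 1:30))
  de <- call_differential(make_records(counts, 1e6),
                          make_records(counts, 1e6))
  expect_true(all(!de$significant))
  expect_true(all(de$p_value > 1 - 1e-9))
})

test_that("ddct_fold implements 2^-ddCt", {
  expect_equal(ddct_fold(0, 0), 1)
  expect_equal(ddct_fold(-1, 0), 2)
  expect_equal(ddct_fold(3.3219, 0), 0.1, tolerance = 1e-3)
  expect_error(ddct_fold(Inf, 0), "finite")
})
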