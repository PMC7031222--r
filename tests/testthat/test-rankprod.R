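# The counting recursion and both tail-probability routes.

test_that("count_tuples_leq matches hand-derived and closed-form cases", {
  expect_identical(count_tuples_leq(1, 5, 3), 3)      # min(n, x)
  expect_identical(count_tuples_leq(2, 3, 3), 5)      # (1,1),(1,2),(2,1),(1,3),(3,1)
  expect_identical(count_tuples_leq(3, 2, 2), 4)      # brute force over 8 tuples
  expect_identical(count_tuples_leq(2, 4, 16), 16)    # all tuples satisfy the bound
  expect_identical(count_tuples_leq(2, 4, 0), 0)
  expect_error(count_tuples_leq(-1, 5, 3), "k must be")
})

test_that("count_tuples_leq equals exhaustive enumeration on a small grid", {
  set.seed(101)
  for (k in 1:3) {
    for (n in c(2, 7, 12)) {
      xs <- unique(c(1, 2, sample.int(n^k, min(6, n^k)), n^k))
      for (x in xs) {
        expect_identical(count_tuples_leq(k, n, x), enum_count_leq(k, n, x))
      }
    }
  }
})

test_that("count accepts decimal-string bounds above 2^53", {
  # T(k, n, n^k) = n^k for any k, n; here n^k ~ 1.1e21
  expect_equal(count_tuples_leq(7, 1000, "1000000000000000000000"), 1000^7)
  expect_error(count_tuples_leq(2, 3, 2^53 * 2), "decimal string")
  expect_error(count_tuples_leq(2, 3, paste(rep("9", 40), collapse = "")),
               "128-bit")
})

test_that("exact p-value matches first principles", {
  expect_equal(rankprod_pvalue_exact(1, 100), 0.01)        # P(R <= 1) = 1/n
  expect_equal(rankprod_pvalue_exact(100, 100), 1)         # max statistic
  expect_equal(rankprod_pvalue_exact(c(1, 1), 3), 1 / 9)   # only (1,1) of 9
  expect_error(rankprod_pvalue_exact(c(0, 2), 5), "ranks must")
  expect_error(rankprod_pvalue_exact(c(1, 6), 5), "ranks must")
})

test_that("p-value bounds are attained exactly across a parameter grid", {
  for (k in c(1, 2, 3, 5, 8)) {
    for (n in c(2, 10, 100, 1000)) {
      p_min <- rankprod_pvalue_exact(rep(1L, k), n)
      p_max <- rankprod_pvalue_exact(rep(n, k), n)
      expect_identical(p_max, 1)
      expect_lte(abs(p_min - n^(-k)), 4 * .Machine$double.eps * n^(-k))
    }
  }
})

test_that("exact p is monotone in each rank", {
  n <- 30
  for (seed in 1:5) {
    set.seed(seed)
    ranks <- sample.int(n, 3, replace = TRUE)
    p0 <- rankprod_pvalue_exact(ranks, n)
    for (i in seq_along(ranks)) {
      if (ranks[i] < n) {
        bumped <- ranks
        bumped[i] <- bumped[i] + 1L
        expect_gte(rankprod_pvalue_exact(bumped, n), p0)
      }
    }
  }
})

test_that("gamma approximation has its closed-form behaviour", {
  expect_identical(rankprod_pvalue_gamma(c(10, 10, 10), 10), 1)  # s = 0
  # k = 1: Q(1, ln(n/r)) = r/n exactly
  for (r in c(1, 7, 25, 99)) {
    expect_equal(rankprod_pvalue_gamma(r, 100), r / 100)
  }
  # midpoint variant shifts u to (r - 0.5)/n
  expect_equal(rankprod_pvalue_gamma(10, 100, continuity = TRUE), 9.5 / 100)
})

test_that("gamma converges to exact at fixed rank quantiles as n grows", {
  quantiles <- c(0.25, 0.55, 0.85)
  relerr <- vapply(c(50, 500, 5000), function(n) {
    ranks <- pmax(1L, as.integer(round(quantiles * n)))
    pe <- rankprod_pvalue_exact(ranks, n)
    pg <- rankprod_pvalue_gamma(ranks, n)
    abs(pg - pe) / pe
  }, numeric(1))
  expect_true(all(diff(relerr) < 0))
  expect_lt(relerr[3], 0.001)
})

test_that("gamma diverges from exact in the deep discrete tail", {
  # small-rank configuration: the continuous approximation overstates the
  # tail by a large factor, which is why exact counting is the default
  # wherever tractable
  pe <- rankprod_pvalue_exact(c(3, 17, 41, 200, 995), 10000)
  pg <- rankprod_pvalue_gamma(c(3, 17, 41, 200, 995), 10000)
  expect_lt(pe, pg)
  expect_gt(abs(pg - pe) / pe, 1)  # not a small-percentage disagreement
})

test_that("null draws give a super-uniform, near-uniform exact p", {
  set.seed(202)
  n <- 500
  p <- replicate(2000, rankprod_pvalue_exact(sample.int(n, 3, replace = TRUE), n))
  expect_gt(mean(p), 0.49)
  expect_lt(mean(p), 0.51)
  # super-uniformity at conventional alpha
  expect_lte(mean(p <= 0.05), 0.06)
})

test_that("dispatch honours method and budget", {
  rp <- rankprod_pvalue(c(1, 2), 10, method = "exact")
  expect_identical(rp$method_used, "exact")
  expect_equal(rp$p, 0.03)
  expect_equal(rp$p, rankprod_pvalue_exact(c(1, 2), 10))

  expect_identical(rankprod_pvalue(c(3, 4), 10, method = "auto")$method_used,
                   "exact")
  # large instance with a tiny budget falls back to gamma
  set.seed(1)
  big <- rankprod_pvalue(sample.int(20000, 150, replace = TRUE), 20000,
                         method = "auto", budget = 10)
  expect_identical(big$method_used, "gamma")
  expect_true(is.na(big$p_exact))
  expect_identical(big$p, big$p_gamma)
  expect_error(rankprod_pvalue(c(9, 9, 9), 10, method = "exact", budget = 1),
               "budget")
})

test_that("the statistic is reported in exact arbitrary-precision form", {
  rp <- rankprod_pvalue(c(2, 3, 5), 10, method = "exact")
  expect_identical(rp$rp, "30")
  expect_identical(rp$rp_num, 30)
  # k = 50 ranks of 1000: product has 150 digits, far beyond double range
  big <- rankprod_pvalue(rep(1000L, 50), 1000, method = "gamma")
  expect_identical(big$rp, paste0("1", strrep("0", 150)))
  expect_true(is.na(big$rp_num))
  expect_equal(big$log_stat, 0)
  expect_identical(big$p_gamma, 1)
})
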