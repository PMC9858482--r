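test_that("Cohen's d matches the pooled-SD definition on toy groups", {
  expect_equal(cohensD(c(1, 2, 3), c(1, 2, 3)), 0)
  expect_equal(cohensD(c(2, 4), c(1, 3)), 1 / sqrt(2), tolerance = 1e-12)
  expect_error(cohensD(1, c(1, 2)), "at least 2")
  expect_true(is.na(cohensD(c(2, 2), c(2, 2))))  # zero pooled SD sentinel
})

test_that("Cohen's d is affine invariant and antisymmetric", {
  set.seed(31)
  for (i in 1:20) {
    x <- stats::rnorm(sample(3:30, 1)); y <- stats::rnorm(sample(3:30, 1), 1)
    a <- stats::runif(1, 0.1, 5); b <- stats::rnorm(1)
    expect_equal(cohensD(a * x + b, a * y + b), cohensD(x, y),
                 tolerance = 1e-10)
    expect_equal(cohensD(y, x), -cohensD(x, y), tolerance = 1e-12)
  }
})

test_that("effect size bands follow the conventional thresholds", {
  expect_identical(effectSizeLabel(c(0.1, -0.1, 0.3, 0.6, -0.7, 0.9, NA)),
                   c("small", "small", "small-medium", "medium", "medium",
                     "large", NA))
})

test_that("one-vs-rest profile has the expected sign structure", {
  set.seed(32)
  n <- 40
  st <- stats::setNames(factor(rep(c("A", "B", "C", "D"), each = 10)),
                        sprintf("s%02d", 1:n))
  ind <- as.numeric(st == "A") + stats::rnorm(n, sd = 1e-4)
  scores <- rbind(indicA = ind, flat = rep(1, n))
  colnames(scores) <- names(st)
  prof <- suppressMessages(oneVsRestProfile(scores, st))
  pa <- prof[prof$feature == "indicA", ]
  expect_gt(pa$d[pa$subtype == "A"], 0)
  expect_true(all(pa$d[pa$subtype != "A"] < 0))
  expect_equal(which.max(abs(pa$d)), which(pa$subtype == "A"))
  # constant feature -> sentinel d, never flagged
  pf <- prof[prof$feature == "flat", ]
  expect_true(all(is.na(pf$d)))
  expect_false(any(pf$significant))
  # FDR >= p within the family, all <= 1
  expect_true(all(prof$fdr >= prof$mwu_p - 1e-12 & prof$fdr <= 1))
})

test_that("one-vs-rest d values cannot share one sign across all subtypes", {
  set.seed(33)
  for (i in 1:10) {
    n <- 60
    st <- stats::setNames(factor(sample(c("A", "B", "C"), n, replace = TRUE,
                                        prob = c(0.5, 0.3, 0.2))),
                          sprintf("s%02d", 1:n))
    while (any(table(st) < 2)) {
      st <- stats::setNames(factor(sample(c("A", "B", "C"), n,
                                          replace = TRUE)), names(st))
    }
    v <- matrix(stats::rnorm(n), 1, n,
                dimnames = list("f", names(st)))
    prof <- oneVsRestProfile(v, st)
    expect_false(all(prof$d > 0) || all(prof$d < 0))
    # brute-force recomputation of each one-vs-rest cell
    for (j in seq_len(nrow(prof))) {
      g1 <- v[1, st == prof$subtype[j]]
      g2 <- v[1, st != prof$subtype[j]]
      expect_equal(prof$d[j], cohensD(g1, g2), tolerance = 1e-12)
    }
  }
})

test_that("planted one-subtype shift of 1 SD is recovered by mean d", {
  set.seed(34)
  ds <- replicate(120, {
    g <- factor(rep(c("A", "rest"), c(50, 150)))
    v <- stats::rnorm(200) + (g == "A") * 1
    cohensD(v[g == "A"], v[g == "rest"])
  })
  expect_lt(abs(mean(ds) - 1), 0.2)
})

test_that("group tests combine Kruskal-Wallis with pairwise MWU stars", {
  set.seed(35)
  v <- c(stats::rnorm(20), stats::rnorm(20, 3), stats::rnorm(20))
  g <- factor(rep(c("A", "B", "C"), each = 20))
  gt <- groupTests(v, g)
  expect_lt(gt$kw_p, 0.001)
  expect_lt(gt$pairwise_p["A", "B"], 0.001)
  expect_identical(gt$pairwise_p["A", "B"], gt$pairwise_p["B", "A"])
  expect_true(is.na(gt$pairwise_p["A", "A"]))
  expect_error(groupTests(v, factor(rep("A", 60))), "2 groups")
})

test_that("identical constant groups give the p = 1 convention and 'ns'", {
  v <- rep(5, 10)
  g <- factor(rep(c("A", "B"), each = 5))
  gt <- groupTests(v, g)
  expect_equal(gt$pairwise_p["A", "B"], 1)
  expect_identical(gt$stars["A", "B"], "ns")
})

test_that("star mapping honors the conventional thresholds", {
  expect_identical(pvalueStars(c(0.2, 0.05, 0.03, 0.01, 0.003, 0.001,
                                 0.0005, 0.0001, 0.00005)),
                   c("ns", "*", "*", "**", "**", "***", "***", "****", "****"))
})

test_that("Kruskal-Wallis p-values are calibrated under the null", {
  set.seed(36)
  ps <- replicate(400, {
    v <- stats::rnorm(45)
    g <- factor(rep(c("A", "B", "C"), each = 15))
    stats::kruskal.test(v, g)$p.value
  })
  hits <- sum(ps < 0.05)
  ci <- stats::binom.test(hits, 400, p = 0.05)$p.value
  expect_gt(ci, 0.01)   # type-I within binomial fluctuation at alpha 0.05
})
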