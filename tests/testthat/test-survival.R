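simSurv <- function(n, beta = 0, x = stats::rnorm(n), cens = 0.3,
                    base = 0.1) {
  t <- stats::rexp(n, base * exp(beta * x))
  horizon <- stats::quantile(t, 1 - cens)
  data.frame(sample_id = sprintf("s%03d", seq_len(n)),
             time = pmin(t, horizon),
             event = as.integer(t <= horizon))
}

test_that("KM estimates are proper step functions and identical groups tie", {
  sv <- data.frame(sample_id = paste0("s", 1:8),
                   time = c(1, 2, 3, 4, 1, 2, 3, 4),
                   event = c(1, 0, 1, 0, 1, 0, 1, 0))
  g <- stats::setNames(factor(rep(c("hi", "lo"), each = 4)), sv$sample_id)
  km <- kmLogrank(g, sv)
  expect_equal(km$logrank_p, 1)

  # group A all events at t = 1, group B all censored at t = 2
  sv2 <- data.frame(sample_id = paste0("s", 1:6),
                    time = c(1, 1, 1, 2, 2, 2),
                    event = c(1, 1, 1, 0, 0, 0))
  g2 <- stats::setNames(factor(rep(c("A", "B"), each = 3)), sv2$sample_id)
  km2 <- kmLogrank(g2, sv2)
  s <- summary(km2$fit, times = 1.5, extend = TRUE)
  expect_equal(s$surv[s$strata == "g=A"], 0)   # A steps to 0 at t = 1
  expect_equal(s$surv[s$strata == "g=B"], 1)   # B stays at 1 (censored only)
  expect_error(kmLogrank(g2[1:3], sv2), "2 groups")
})

test_that("log-rank rejects a hazard ratio of 2 with good power", {
  set.seed(61)
  rejections <- replicate(150, {
    n <- 200
    g <- rep(c(0, 1), each = 100)
    t <- stats::rexp(n, 0.1 * 2^g)
    sv <- data.frame(sample_id = sprintf("s%03d", 1:n),
                     time = pmin(t, stats::quantile(t, 0.8)),
                     event = as.integer(t <= stats::quantile(t, 0.8)))
    gg <- stats::setNames(factor(g), sv$sample_id)
    kmLogrank(gg, sv)$logrank_p < 0.05
  })
  expect_gte(mean(rejections), 0.8)
})

test_that("Cox screening recovers direction and skips degenerate inputs", {
  set.seed(62)
  n <- 150
  x <- stats::rnorm(n)
  sv <- simSurv(n, beta = 0.8, x = x)
  ab <- rbind(risky = x, flat = rep(1, n))
  colnames(ab) <- sv$sample_id
  expect_warning(out <- coxScreen(ab, sv), "constant")
  expect_identical(out$cell, "risky")
  expect_gt(out$log_hr, 0)
  expect_true(out$ci_low <= out$hr && out$hr <= out$ci_high)

  # no events -> skipped
  sv0 <- sv; sv0$event <- 0
  expect_warning(out0 <- coxScreen(ab["risky", , drop = FALSE], sv0),
                 "no events")
  expect_null(out0)
})

test_that("optimal cutoff lands between separated risk clusters", {
  set.seed(63)
  # low values die early, high values survive long
  v <- stats::setNames(c(stats::runif(15, 0, 1), stats::runif(15, 3, 4)),
                       sprintf("s%03d", 1:30))
  sv <- data.frame(sample_id = names(v),
                   time = ifelse(v < 2, stats::runif(30, 0.1, 1),
                                 stats::runif(30, 5, 10)),
                   event = 1)
  cut <- optimalCutoff(v, sv, minprop = 0.1)
  # cutoff is an observed value; the induced split separates the clusters
  expect_equal(cut$n_high, 15)
  expect_setequal(names(v)[v > cut$cutoff], names(v)[v >= 3])
  expect_lt(cut$cutoff, 3)
  expect_identical(cut$direction, "high")   # high values live longer
  expect_true(cut$selection_biased)
  expect_lt(cut$logrank_p, 1e-4)
})

test_that("minprop = 0.5 on n = 10 leaves only the median split", {
  v <- stats::setNames(1:10, sprintf("s%02d", 1:10))
  sv <- data.frame(sample_id = names(v), time = stats::runif(10, 1, 5),
                   event = rep(c(0, 1), 5))
  cut <- optimalCutoff(v, sv, minprop = 0.5)
  expect_equal(cut$n_high, 5)
  expect_equal(cut$n_low, 5)
  expect_equal(cut$cutoff, 5)
})

test_that("cutoff grouping is invariant to monotone transforms of values", {
  set.seed(64)
  v <- stats::setNames(stats::rnorm(40), sprintf("s%03d", 1:40))
  sv <- simSurv(40, beta = 1, x = v)
  c1 <- optimalCutoff(v, sv)
  c2 <- optimalCutoff(stats::setNames(exp(v), names(v)), sv)
  expect_equal(c2$n_high, c1$n_high)
  expect_equal(c2$statistic, c1$statistic, tolerance = 1e-10)
  expect_equal(c2$logrank_p, c1$logrank_p, tolerance = 1e-10)
})

test_that("the naive post-selection log-rank p is anti-conservative", {
  set.seed(65)
  ps <- replicate(200, {
    v <- stats::setNames(stats::rnorm(40), sprintf("s%03d", 1:40))
    sv <- simSurv(40, beta = 0, x = v)   # values independent of survival
    optimalCutoff(v, sv, minprop = 0.1)$logrank_p
  })
  expect_gt(mean(ps < 0.05), 0.15)   # far above the nominal 5%
})

test_that("Cox and log-rank agree on direction for a binary covariate", {
  set.seed(66)
  n <- 120
  grp <- rep(c(0, 1), each = n / 2)
  t <- stats::rexp(n, 0.1 * exp(1.2 * grp))
  sv <- data.frame(sample_id = sprintf("s%03d", 1:n), time = t, event = 1)
  ab <- matrix(grp, 1, n, dimnames = list("cellX", sv$sample_id))
  cox <- coxScreen(ab, sv)
  g <- stats::setNames(factor(ifelse(grp == 1, "high", "low")), sv$sample_id)
  km <- kmLogrank(g, sv)
  expect_gt(cox$log_hr, 0)        # high abundance is the risky group
  expect_lt(km$logrank_p, 0.01)
})
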