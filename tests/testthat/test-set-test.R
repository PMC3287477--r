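mk_summary <- function(measures, prefix = "g") {
  data.frame(gene_id = paste0(prefix, seq_along(measures)),
             measure = measures, baseline_measure = measures,
             stringsAsFactors = FALSE)
}

test_that("Welch set statistic matches the independent two-sample oracle", {
  gs <- mk_summary(c(1.0, 1.5, 2.0, 2.5, 2.0, 3.0, 4.0, 5.0, 6.0))
  sets <- list(A = paste0("g", 1:4))
  res <- prage_set_test(gs, sets, min_set_size = 2)
  tt <- t.test(c(1.0, 1.5, 2.0, 2.5), c(2.0, 3.0, 4.0, 5.0, 6.0),
               alternative = "less", var.equal = FALSE)
  expect_equal(res$statistic, unname(tt$statistic), tolerance = 1e-12)
  expect_equal(res$df, unname(tt$parameter), tolerance = 1e-12)
  expect_equal(res$pvalue, tt$p.value, tolerance = 1e-12)
})

test_that("set identical to complement gives t = 0, one-sided p = 0.5", {
  gs <- mk_summary(rep(c(1, 2, 3, 4, 5), 2))
  res <- prage_set_test(gs, list(A = paste0("g", 1:5)), min_set_size = 2)
  expect_equal(res$statistic, 0)
  expect_equal(res$pvalue, 0.5)
  # equal variances and sizes: Satterthwaite df reduces to 2(N-1)
  expect_equal(res$df, 2 * (5 - 1))
})

test_that("the set test is invariant to affine rescaling of measures", {
  set.seed(501)
  x <- rexp(60)
  gs1 <- mk_summary(x)
  gs2 <- mk_summary(3.7 * x + 11)
  sets <- list(A = paste0("g", 1:15), B = paste0("g", 30:55))
  r1 <- prage_set_test(gs1, sets)
  r2 <- prage_set_test(gs2, sets)
  expect_equal(r1$statistic, r2$statistic, tolerance = 1e-10)
  expect_equal(r1$df, r2$df, tolerance = 1e-10)
  expect_equal(r1$pvalue, r2$pvalue, tolerance = 1e-10)
})

test_that("small sets are flagged and excluded from q-values; tiny ones error", {
  set.seed(502)
  gs <- mk_summary(rexp(40))
  sets <- list(big = paste0("g", 1:15), small = paste0("g", 16:21),
               tiny = "g39", empty = c("nope1", "nope2"))
  res <- prage_set_test(gs, sets, min_set_size = 10)
  expect_false(res$flagged_small[1])
  expect_true(res$flagged_small[2])
  expect_true(is.na(res$qvalue[2]))
  expect_false(is.na(res$pvalue[2]))   # p still computed
  expect_match(res$error[3], "fewer than 2")
  expect_match(res$error[4], "fewer than 2")
})

test_that("the one-sided test holds its level under the global null", {
  set.seed(503)
  sets <- list(A = paste0("g", 1:20))
  n_rep <- 500
  level_at <- function(rmeasure) {
    hits05 <- hits01 <- 0
    for (r in seq_len(n_rep)) {
      gs <- mk_summary(rmeasure(100))
      p <- prage_set_test(gs, sets)$pvalue
      hits05 <- hits05 + (p < 0.05)
      hits01 <- hits01 + (p < 0.01)
    }
    c(hits05, hits01) / n_rep
  }
  # normal measures: exact t calibration, binomial 3-SE band
  lv <- level_at(rnorm)
  expect_lt(abs(lv[1] - 0.05), 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(abs(lv[2] - 0.01), 3 * sqrt(0.01 * 0.99 / n_rep))
  # strongly right-skewed measures: the one-sided t at N=20 carries a small
  # known upward level error; it must stay modest, not explode
  lv_sk <- level_at(rexp)
  expect_gt(lv_sk[1], 0.05 - 3 * sqrt(0.05 * 0.95 / n_rep))
  expect_lt(lv_sk[1], 0.15)
})

test_that("Z-statistic baseline matches its location model", {
  gs <- mk_summary(c(rep(2, 10), 1, 3))
  res <- zmethod_set_test(gs, list(A = paste0("g", 1:10)), min_set_size = 2)
  expect_equal(res$statistic, 0)  # set mean equals global mean
  expect_equal(res$pvalue, 0.5)

  set.seed(504)
  zbar <- mean(replicate(800, {
    meas <- rnorm(500)
    idx <- 1:25
    meas[idx] <- meas[idx] + 0.4
    gs <- mk_summary(meas)
    zmethod_set_test(gs, list(A = paste0("g", idx)), min_set_size = 2)$statistic
  }))
  expect_equal(zbar, 2.0, tolerance = 0.1)

  expect_error(zmethod_set_test(mk_summary(5), list(A = "g1")), "at least 2")
  expect_error(zmethod_set_test(mk_summary(c(2, 2, 2)), list(A = "g1")),
               "zero variance")
})

test_that("Storey q-values: trivial cases and the BH oracle", {
  expect_lte(qvalues(0.04), 0.04)
  expect_equal(qvalues(numeric(0)), numeric(0))
  q <- qvalues(rep(0.2, 10))
  expect_true(all(q == q[1]))

  p <- c(0.001, 0.01, 0.5, 0.9)
  expect_equal(qvalues(p, pi0 = 1), p.adjust(p, method = "BH"))
  set.seed(505)
  p2 <- c(runif(30)^2, runif(10))
  expect_equal(qvalues(p2, pi0 = 1), p.adjust(p2, method = "BH"))

  # monotonicity: q ordering follows p ordering, and thresholding is nested
  q2 <- qvalues(p2)
  expect_true(all(diff(q2[order(p2)]) >= -1e-12))
  expect_true(all(which(q2 <= 0.01) %in% which(q2 <= 0.05)))
  expect_error(qvalues(c(0.5, 0)), "\\(0, 1\\]")
})

test_that("normality diagnostic separates set sizes 5 and 20", {
  set.seed(506)
  skewed <- rexp(150)
  diag_sk <- normality_diagnostic(skewed, set_sizes = c(5, 20),
                                  n_draws = 400, seed = 1)
  # heavier violation for tiny sets on skewed measures
  expect_lt(diag_sk[["5"]]$shapiro_p, diag_sk[["20"]]$shapiro_p)
  expect_lt(diag_sk[["5"]]$shapiro_p, 0.01)

  normal_meas <- rnorm(150)
  rejections <- sum(replicate(20, {
    d <- normality_diagnostic(normal_meas, set_sizes = 20, n_draws = 300)
    d[["20"]]$shapiro_p < 0.01
  }))
  expect_lte(rejections / 20, 0.05)

  expect_error(normality_diagnostic(rep(1, 50), set_sizes = 5, n_draws = 100),
               "degenerate")
  expect_error(normality_diagnostic(rnorm(10), set_sizes = 20, n_draws = 100),
               "exceeds")
})
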