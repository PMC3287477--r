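test_that("qc_filter applies the MAF, missingness and HWE rules", {
  set.seed(101)
  n <- 200
  good <- replicate(3, rand_dosage(n, 0.3), simplify = FALSE)
  mono <- list(rep(0, n))                         # MAF 0 -> maf rule
  rare <- list(c(1, rep(0, n - 1)))               # MAF 1/400 < 0.01
  holey <- list(c(rep(NA, 25), rand_dosage(n - 25, 0.3)))  # 12.5% missing
  hwe_bad <- list(rep(c(0, 2), n / 2))            # no hets at freq 0.5
  g <- make_geno(c(good, mono, rare, holey, hwe_bad))
  res <- qc_filter(g, maf_min = 0.01, miss_max = 0.05, hwe_alpha = 1e-6)
  expect_setequal(res$exclusions$snp_id, c("s04", "s05", "s06", "s07"))
  expect_equal(res$exclusions$rule[res$exclusions$snp_id == "s04"], "maf")
  expect_equal(res$exclusions$rule[res$exclusions$snp_id == "s06"], "missingness")
  expect_equal(res$exclusions$rule[res$exclusions$snp_id == "s07"], "hwe")
  expect_equal(ncol(res$genotypes$dosages), 3)

  # exact HWE proportions are retained: chi-square is identically 0
  g2 <- make_geno(list(counts_to_dosage(50, 100, 50)))
  expect_equal(hwe_chisq_p(50, 100, 50), 1)
  expect_equal(nrow(qc_filter(g2)$exclusions), 0)
})

test_that("qc_filter is idempotent and errors when nothing survives", {
  set.seed(102)
  g <- make_geno(replicate(6, rand_dosage(150, 0.25), simplify = FALSE))
  once <- qc_filter(g)$genotypes
  twice <- qc_filter(once)
  expect_equal(nrow(twice$exclusions), 0)
  expect_identical(twice$genotypes$dosages, once$dosages)

  all_mono <- make_geno(list(rep(0, 50), rep(2, 50)))
  expect_error(qc_filter(all_mono), "no markers survive")
})

test_that("HWE uses controls only when a phenotype is supplied", {
  # controls in perfect HWE, cases wildly out: SNP must survive
  set.seed(107)
  ctrl <- counts_to_dosage(25, 50, 25)
  case <- rep(c(0, 2), 50)
  g <- make_geno(list(c(ctrl, case), rand_dosage(200, 0.4)))
  ph <- make_pheno(g, c(rep(0, 100), rep(1, 100)))
  res <- qc_filter(g, hwe_alpha = 0.05, phenotype = ph)
  expect_false("s01" %in% res$exclusions$snp_id)
  # without the phenotype the pooled counts fail HWE at the same threshold
  res2 <- qc_filter(g, hwe_alpha = 0.05)
  expect_true("s01" %in% res2$exclusions$snp_id)
})

test_that("fast scan matches the trend-test oracle on a 2x3 table", {
  # cases (0,1,2 copies): 10,20,10; controls: 20,20,0
  dose <- c(counts_to_dosage(10, 20, 10), counts_to_dosage(20, 20, 0))
  status <- c(rep(1, 40), rep(0, 40))
  g <- make_geno(list(dose))
  res <- snp_logistic_scan(g, make_pheno(g, status), fast = TRUE)

  # independent oracle: score statistic assembled from the contingency table
  oracle_score <- function(cases, controls) {
    x <- c(0, 1, 2)
    n_g <- cases + controls
    N <- sum(n_g); R <- sum(cases)
    ybar <- R / N
    u <- sum(x * (cases - n_g * ybar))
    gbar <- sum(x * n_g) / N
    v <- ybar * (1 - ybar) * sum(n_g * (x - gbar)^2)
    u^2 / v
  }
  x2 <- oracle_score(c(10, 20, 10), c(20, 20, 0))
  expect_equal(res$statistic, x2, tolerance = 1e-12)
  expect_equal(res$pvalue, pchisq(x2, 1, lower.tail = FALSE), tolerance = 1e-12)

  # and against the stock Cochran-Armitage implementation
  pt <- stats::prop.trend.test(c(10, 20, 10), c(30, 40, 10))
  expect_equal(res$statistic, unname(pt$statistic), tolerance = 1e-10)
})

test_that("scan p-values are invariant to allele-coding swap g -> 2 - g", {
  set.seed(103)
  g1 <- make_geno(replicate(5, rand_dosage(120, 0.3), simplify = FALSE))
  g2 <- genotype_matrix(2 - g1$dosages, g1$snp_meta, g1$sample_ids)
  ph <- make_pheno(g1, rbinom(120, 1, 0.5))
  for (fast in c(TRUE, FALSE)) {
    p1 <- snp_logistic_scan(g1, ph, fast = fast)$pvalue
    p2 <- snp_logistic_scan(g2, ph, fast = fast)$pvalue
    expect_equal(p1, p2, tolerance = 1e-8)
  }
})

test_that("fast and full modes agree without covariates; flags are set", {
  set.seed(104)
  n <- 600
  g <- make_geno(c(replicate(8, rand_dosage(n, runif(1, 0.2, 0.4)),
                             simplify = FALSE),
                   list(rep(1, n))))  # constant het: monomorphic
  ph <- make_pheno(g, rbinom(n, 1, 0.5))
  fast <- snp_logistic_scan(g, ph, fast = TRUE)
  full <- snp_logistic_scan(g, ph, fast = FALSE)
  expect_equal(fast$status_flag[9], "monomorphic")
  expect_equal(full$status_flag[9], "monomorphic")
  expect_true(all(is.na(fast$pvalue[9])))
  ok <- fast$status_flag == "ok"
  expect_equal(fast$pvalue[ok], full$pvalue[ok], tolerance = 0.1)
})

test_that("null p-values are uniform (Kolmogorov-Smirnov)", {
  set.seed(105)
  n <- 500
  g <- make_geno(replicate(200, rand_dosage(n, runif(1, 0.1, 0.5)),
                           simplify = FALSE))
  ph <- make_pheno(g, rbinom(n, 1, 0.5))  # independent of genotypes
  res <- snp_logistic_scan(g, ph, fast = TRUE)
  ks <- suppressWarnings(stats::ks.test(res$pvalue, "punif"))
  expect_gt(ks$p.value, 0.01)
})

test_that("full mode flags separation and names collinear covariates", {
  set.seed(106)
  n <- 80
  sep <- c(rep(0, 40), rep(2, 40))     # dosage determines status exactly
  g <- make_geno(list(sep, rand_dosage(n, 0.3)))
  ph <- make_pheno(g, c(rep(0, 40), rep(1, 40)))
  res <- snp_logistic_scan(g, ph, fast = FALSE)
  expect_equal(res$status_flag[1], "separation")
  expect_true(is.na(res$pvalue[1]))
  expect_equal(res$status_flag[2], "ok")

  ph2 <- make_pheno(g, c(rep(0, 40), rep(1, 40)),
                    age = rnorm(n), age2 = NA)
  ph2$age2 <- 2 * ph2$age  # exactly collinear
  expect_error(snp_logistic_scan(g, ph2, fast = FALSE), "age2")
})

test_that("scan requires both phenotype classes", {
  g <- make_geno(list(rand_dosage(30, 0.3)))
  expect_error(snp_logistic_scan(g, make_pheno(g, rep(1, 30))),
               "phenotype class")
})
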