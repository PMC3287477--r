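test_that("pairwise_r2 matches a hand-coded Pearson oracle and its limits", {
  x <- c(0, 0, 1, 1, 2, 2)
  y <- c(0, 1, 0, 1, 2, 2)
  # arithmetic oracle: r^2 from raw sums
  n <- length(x)
  num <- sum(x * y) - n * mean(x) * mean(y)
  den <- sqrt((sum(x^2) - n * mean(x)^2) * (sum(y^2) - n * mean(y)^2))
  expect_equal(pairwise_r2(x, y), (num / den)^2, tolerance = 1e-12)

  expect_equal(pairwise_r2(x, x), 1)
  expect_equal(pairwise_r2(x, 2 - x), 1)  # correlation -1, squared
  expect_error(pairwise_r2(x, rep(1, 6), y_id = "rs99"), "rs99")
})

test_that("greedy LD blocking matches step-by-step application of the rule", {
  set.seed(301)
  n <- 400
  # 5 SNPs: columns 1-2 near-duplicates, 3 independent, 4-5 near-duplicates
  a <- rand_dosage(n, 0.3); b <- rand_dosage(n, 0.4); c_ <- rand_dosage(n, 0.3)
  x <- cbind(a, flip(a, 8), b, c_, flip(c_, 8))
  part <- build_ld_blocks(x, r2_threshold = 0.05)

  # brute-force scan applying the rule
  r2m <- cor(x)^2
  blocks <- list(1L)
  for (k in 2:5) {
    cur <- blocks[[length(blocks)]]
    if (any(r2m[k, cur] > 0.05)) {
      blocks[[length(blocks)]] <- c(cur, k)
    } else {
      blocks[[length(blocks) + 1L]] <- k
    }
  }
  expect_equal(lapply(part$blocks, as.integer), lapply(blocks, as.integer))
  expect_equal(lengths(part$blocks), c(2L, 1L, 2L))
})

test_that("all-correlated and all-independent extremes block correctly", {
  set.seed(302)
  a <- rand_dosage(300, 0.4)
  same <- build_ld_blocks(cbind(a, a, 2 - a, a))
  expect_length(same$blocks, 1)
  expect_equal(lengths(same$blocks), 4L)
  expect_gt(same$rho[1], 0.95)

  ind <- build_ld_blocks(sapply(1:4, function(i) rand_dosage(300, 0.4)))
  expect_length(ind$blocks, 4)
  expect_equal(ind$rho, rep(0, 4), tolerance = 1e-12)
})

test_that("closed-form CS rho MLE equals 1-d numerical likelihood search", {
  set.seed(303)
  for (rho_true in c(0.2, 0.6)) {
    x <- cs_block_dosages(500, 6, rho_true, 0.3)
    xs <- scale(x, scale = apply(x, 2, function(v) sqrt(mean(v^2) - mean(v)^2)))
    s <- crossprod(xs) / nrow(xs)
    t2 <- sum(s)
    ll <- function(r) {
      R <- (1 - r) * diag(6) + r
      -nrow(xs) / 2 * (6 * log(2 * pi) + determinant(R)$modulus[1] +
                         sum(diag(solve(R, s))))
    }
    opt <- optimize(ll, c(0, 0.999), maximum = TRUE)$maximum
    expect_equal(cs_rho_mle(t2, 6), opt, tolerance = 1e-4)
  }
})

test_that("AIC selects the generating covariance structure", {
  set.seed(304)
  # independent data: IND wins despite CS/LD-CS having higher likelihood
  n_ind <- 0
  for (r in 1:40) {
    x <- sapply(1:10, function(i) rand_dosage(2000, 0.3))
    fit <- fit_cov_structure(x, build_ld_blocks(x))
    if (fit$selected == "IND") n_ind <- n_ind + 1
  }
  expect_gte(n_ind / 40, 0.9)

  # exchangeable data with rho 0.6: CS (or equal-likelihood LD-CS) wins,
  # and rho is recovered within 0.05
  n_cs <- 0
  rho_hat <- numeric(20)
  for (r in 1:20) {
    x <- cs_block_dosages(2000, 8, 0.707, 0.3)  # latent 0.707 -> dosage ~0.6
    fit <- fit_cov_structure(x, build_ld_blocks(x))
    if (fit$selected %in% c("CS", "LD-CS")) n_cs <- n_cs + 1
    rho_hat[r] <- fit$partition$rho[1]
    # oracle for the dosage-scale rho this copula induces
  }
  expect_gte(n_cs / 20, 0.9)
  dosage_rho <- mean(replicate(30, mean(cor(cs_block_dosages(2000, 8, 0.707, 0.3))
                                        [upper.tri(diag(8))])))
  expect_equal(mean(rho_hat), dosage_rho, tolerance = 0.05)
})

test_that("single-SNP gene collapses all structures to IND", {
  x <- matrix(rand_dosage(100, 0.3), ncol = 1)
  fit <- fit_cov_structure(x, build_ld_blocks(x))
  expect_equal(fit$selected, "IND")
  expect_equal(effective_gene_size(fit$partition), 1)
})

test_that("effective gene size respects its limits and monotonicity", {
  mkpart <- function(sizes, rho) {
    idx <- split(seq_len(sum(sizes)), rep(seq_along(sizes), sizes))
    structure(list(blocks = unname(idx), rho = rho, n_snps = sum(sizes)),
              class = "ld_partition")
  }
  # all singletons: n_eff = gene size under any formula
  expect_equal(effective_gene_size(mkpart(rep(1, 10), rep(0, 10))), 10)
  # perfect LD collapses a block to ~1 effective SNP
  expect_equal(effective_gene_size(mkpart(5, 0.9999)), 1, tolerance = 0.05)
  expect_equal(effective_gene_size(mkpart(5, 0.9999), method = "design_effect"),
               1, tolerance = 1e-3)
  # committed arithmetic of the design-effect variant
  expect_equal(effective_gene_size(mkpart(c(4, 2), c(0.5, 0)),
                                   method = "design_effect"), 4 / 2.5 + 2)
  # bounds and monotonicity in rho for both strategies
  for (meth in c("galwey", "design_effect")) {
    sizes <- c(4, 7)
    prev <- Inf
    for (rho in seq(0, 0.95, by = 0.05)) {
      ne <- effective_gene_size(mkpart(sizes, rep(rho, 2)), method = meth)
      expect_lte(ne, sum(sizes) + 1e-9)
      expect_gte(ne, length(sizes) - 1e-9)
      expect_lte(ne, prev + 1e-9)
      prev <- ne
    }
  }
  expect_error(effective_gene_size(mkpart(3, 1.0)), "\\[0, 1\\)")
})

test_that("blocking depends only on SNP order, not absolute positions", {
  set.seed(305)
  x <- cbind(cs_block_dosages(300, 3, 0.7, 0.3), rand_dosage(300, 0.3))
  g1 <- make_geno(lapply(seq_len(4), function(j) x[, j]), start = 1000L)
  g2 <- make_geno(lapply(seq_len(4), function(j) x[, j]), start = 999000L)
  p1 <- build_ld_blocks(g1$dosages)
  p2 <- build_ld_blocks(g2$dosages)
  expect_identical(p1$blocks, p2$blocks)
  expect_equal(p1$rho, p2$rho)
})
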