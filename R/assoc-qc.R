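#' Hardy-Weinberg goodness-of-fit p-value
#'
#' One-degree-of-freedom Pearson chi-square comparing observed genotype
#' counts to the binomial expectation at the sample allele frequency.
#' Monomorphic markers return p = 1 (no test possible).
#'
#' @param n0,n1,n2 counts of genotypes with 0, 1 and 2 copies of the minor
#'   allele. Vectorised.
#' @return p-values in (0, 1].
#' @export
hwe_chisq_p <- function(n0, n1, n2) {
  n <- n0 + n1 + n2
  p <- (n1 + 2 * n2) / (2 * n)
  q <- 1 - p
  e0 <- n * q^2
  e1 <- 2 * n * p * q
  e2 <- n * p^2
  x2 <- rep(0, length(n))
  ok <- p > 0 & p < 1 & n > 0
  x2[ok] <- (n0[ok] - e0[ok])^2 / e0[ok] +
    (n1[ok] - e1[ok])^2 / e1[ok] +
    (n2[ok] - e2[ok])^2 / e2[ok]
  pv <- stats::pchisq(x2, df = 1, lower.tail = FALSE)
  pmax(pv, .Machine$double.xmin)
}

#' Marker quality control
#'
#' Drops SNPs by three standard GWAS filters, with defaults matching common
#' array-QC practice: call-rate (missingness > `miss_max`), minor allele
#' frequency (< `maf_min`, which also removes monomorphic markers), and
#' Hardy-Weinberg disequilibrium (chi-square p < `hwe_alpha`). When a
#' phenotype is supplied the HWE test uses controls only, the usual
#' case-control convention; otherwise all samples.
#'
#' Filters are checked in the order missingness, MAF, HWE and the exclusion
#' log records the first rule each dropped SNP failed.
#'
#' @param g a [genotype_matrix()].
#' @param maf_min minimum minor allele frequency, in (0, 1).
#' @param miss_max maximum per-SNP missing fraction, in (0, 1).
#' @param hwe_alpha Hardy-Weinberg p-value threshold, in (0, 1).
#' @param phenotype optional phenotype table (`sample_id`, `status`) used to
#'   restrict the HWE test to controls.
#' @return list with `genotypes` (the filtered [genotype_matrix()]) and
#'   `exclusions` (data frame `snp_id`, `rule`, `value`).
#' @export
qc_filter <- function(g, maf_min = 0.01, miss_max = 0.05, hwe_alpha = 1e-6,
                      phenotype = NULL) {
  stopifnot(inherits(g, "genotype_matrix"))
  for (thr in c(maf_min, miss_max, hwe_alpha)) {
    if (!is.numeric(thr) || thr <= 0 || thr >= 1) {
      stop("QC thresholds must lie in (0, 1)")
    }
  }
  dos <- g$dosages
  miss <- colMeans(is.na(dos))
  p_alt <- colMeans(dos, na.rm = TRUE) / 2
  p_alt[is.nan(p_alt)] <- 0  # all-missing column: caught by miss filter
  maf <- pmin(p_alt, 1 - p_alt)

  hwe_rows <- seq_len(nrow(dos))
  if (!is.null(phenotype)) {
    status <- phenotype$status[match(g$sample_ids, phenotype$sample_id)]
    if (anyNA(status)) stop("phenotype table does not cover all samples")
    hwe_rows <- which(status == 0)
  }
  sub <- dos[hwe_rows, , drop = FALSE]
  n0 <- colSums(sub == 0, na.rm = TRUE)
  n1 <- colSums(sub == 1, na.rm = TRUE)
  n2 <- colSums(sub == 2, na.rm = TRUE)
  hwe_p <- hwe_chisq_p(n0, n1, n2)

  rule <- rep(NA_character_, ncol(dos))
  value <- rep(NA_real_, ncol(dos))
  hit <- function(cond, name, val) {
    new <- is.na(rule) & cond
    rule[new] <<- name
    value[new] <<- val[new]
  }
  hit(miss > miss_max, "missingness", miss)
  hit(maf < maf_min, "maf", maf)
  hit(hwe_p < hwe_alpha, "hwe", hwe_p)

  drop <- !is.na(rule)
  if (all(drop)) stop("no markers survive QC")
  exclusions <- data.frame(snp_id = g$snp_meta$snp_id[drop],
                           rule = rule[drop], value = value[drop],
                           stringsAsFactors = FALSE)
  meta_kept <- g$snp_meta[!drop, , drop = FALSE]
  rownames(meta_kept) <- NULL
  kept <- .genotype_matrix_unsafe(dos[, !drop, drop = FALSE],
                                  meta_kept, g$sample_ids)
  list(genotypes = kept, exclusions = exclusions)
}

#' Per-SNP additive association scan
#'
#' Tests each SNP for association with a binary phenotype under the additive
#' (allele-dosage) model, one degree of freedom. Two modes:
#'
#' * `fast = TRUE`: the logistic score test without covariates, identical to
#'   the Cochran-Armitage trend test on the 2x3 genotype-by-status table.
#'   Vectorised over SNPs; `beta_hat` is the one-step (score/information)
#'   log-odds estimate.
#' * `fast = FALSE`: per-SNP logistic regression with the covariate columns
#'   of `phenotype`, reporting the Wald 1-df p-value for the dosage term.
#'
#' Missing dosages are handled by per-SNP complete-case analysis.
#' Monomorphic SNPs are flagged (`status_flag = "monomorphic"`) and carry no
#' p-value; complete separation in full mode is flagged `"separation"`.
#'
#' @param g a [genotype_matrix()].
#' @param phenotype phenotype table with `sample_id`, `status` and, for the
#'   full mode, covariate columns.
#' @param fast logical; score test (no covariates) vs per-SNP logistic fit.
#' @return data frame with one row per SNP: `snp_id`, `beta_hat`,
#'   `statistic` (chi-square, 1 df), `pvalue`, `status_flag`.
#' @export
snp_logistic_scan <- function(g, phenotype, fast = TRUE) {
  stopifnot(inherits(g, "genotype_matrix"))
  status <- phenotype$status[match(g$sample_ids, phenotype$sample_id)]
  if (anyNA(status)) stop("phenotype table does not cover all samples")
  if (min(table(factor(status, levels = 0:1))) < 2) {
    stop("need at least 2 samples in each phenotype class")
  }
  if (fast) {
    .scan_score(g, status)
  } else {
    .scan_glm(g, status, phenotype)
  }
}

# Logistic score test with intercept-only null: U = g'(y - ybar),
# V = ybar (1 - ybar) * sum (g - gbar)^2, X2 = U^2 / V ~ chisq_1.
.scan_score <- function(g, status) {
  dos <- g$dosages
  y <- as.numeric(status)
  n_snp <- ncol(dos)
  has_na <- anyNA(dos)
  if (!has_na) {
    n <- nrow(dos)
    ybar <- mean(y)
    u <- as.numeric(crossprod(dos, y - ybar))
    ssg <- colSums(dos^2) - n * (colMeans(dos))^2
    v <- ybar * (1 - ybar) * ssg
  } else {
    u <- v <- ssg <- numeric(n_snp)
    for (j in seq_len(n_snp)) {
      ok <- !is.na(dos[, j])
      gj <- dos[ok, j]
      yj <- y[ok]
      ybar <- mean(yj)
      u[j] <- sum(gj * (yj - ybar))
      ssg[j] <- sum((gj - mean(gj))^2)
      v[j] <- ybar * (1 - ybar) * ssg[j]
    }
  }
  mono <- ssg <= 0
  stat <- ifelse(mono, NA_real_, u^2 / v)
  pval <- ifelse(mono, NA_real_,
                 pmax(stats::pchisq(stat, 1, lower.tail = FALSE),
                      .Machine$double.xmin))
  data.frame(
    snp_id = g$snp_meta$snp_id,
    beta_hat = ifelse(mono, NA_real_, u / v),
    statistic = stat,
    pvalue = pval,
    status_flag = ifelse(mono, "monomorphic", "ok"),
    stringsAsFactors = FALSE
  )
}

.scan_glm <- function(g, status, phenotype) {
  covars <- phenotype[, setdiff(names(phenotype), c("sample_id", "status")),
                      drop = FALSE]
  covars <- covars[match(g$sample_ids, phenotype$sample_id), , drop = FALSE]
  if (ncol(covars)) {
    mm <- stats::model.matrix(~ ., data = covars)
    qr_mm <- qr(mm)
    if (qr_mm$rank < ncol(mm)) {
      dropped <- colnames(mm)[qr_mm$pivot[(qr_mm$rank + 1):ncol(mm)]]
      stop("collinear covariate column(s): ", paste(dropped, collapse = ", "))
    }
  } else {
    mm <- stats::model.matrix(~ 1, data = data.frame(row.names = seq_along(status)))
  }
  dos <- g$dosages
  n_snp <- ncol(dos)
  beta <- stat <- pval <- rep(NA_real_, n_snp)
  flag <- rep("ok", n_snp)
  for (j in seq_len(n_snp)) {
    ok <- !is.na(dos[, j])
    gj <- dos[ok, j]
    if (length(unique(gj)) < 2) {
      flag[j] <- "monomorphic"
      next
    }
    dat <- data.frame(y = status[ok], gdose = gj, mm[ok, -1, drop = FALSE])
    fit <- suppressWarnings(stats::glm(y ~ ., data = dat, family = stats::binomial()))
    co <- summary(fit)$coefficients
    if (!"gdose" %in% rownames(co) || !fit$converged ||
        co["gdose", "Std. Error"] > 50) {
      flag[j] <- "separation"
      next
    }
    beta[j] <- co["gdose", "Estimate"]
    z <- co["gdose", "z value"]
    stat[j] <- z^2
    pval[j] <- max(stats::pchisq(z^2, 1, lower.tail = FALSE),
                   .Machine$double.xmin)
  }
  data.frame(snp_id = g$snp_meta$snp_id, beta_hat = beta, statistic = stat,
             pvalue = pval, status_flag = flag, stringsAsFactors = FALSE)
}

#' Write per-SNP association results to TSV
#'
#' @param assoc data frame from [snp_logistic_scan()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_snp_results <- function(assoc, path) {
  utils::write.table(assoc, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
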