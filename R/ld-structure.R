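#' Pairwise composite LD (r-squared) between two dosage vectors
#'
#' Squared Pearson correlation of additive dosages, the standard
#' genotype-scale (composite) LD measure. Missing entries are dropped
#' pairwise.
#'
#' @param x,y numeric dosage vectors of equal length >= 3.
#' @param x_id,y_id identifiers used in error messages.
#' @return r-squared in \[0, 1\].
#' @export
pairwise_r2 <- function(x, y, x_id = "x", y_id = "y") {
  if (length(x) != length(y)) stop("dosage vectors differ in length")
  ok <- !is.na(x) & !is.na(y)
  if (sum(ok) < 3) stop("need at least 3 complete pairs")
  if (stats::var(x[ok]) == 0) stop("zero-variance dosage vector: ", x_id)
  if (stats::var(y[ok]) == 0) stop("zero-variance dosage vector: ", y_id)
  stats::cor(x[ok], y[ok])^2
}

# Mean-impute missing entries, center, and scale to unit ML (1/n) variance.
# Zero-variance columns are an error naming the SNP.
.standardize_dosages <- function(x) {
  x <- as.matrix(x)
  n <- nrow(x)
  if (anyNA(x)) {
    for (j in seq_len(ncol(x))) {
      nas <- is.na(x[, j])
      if (any(nas)) x[nas, j] <- mean(x[, j], na.rm = TRUE)
    }
  }
  mu <- colMeans(x)
  s2 <- colMeans(x^2) - mu^2
  if (any(s2 <= 0)) {
    bad <- colnames(x)[s2 <= 0]
    if (is.null(bad)) bad <- which(s2 <= 0)
    stop("zero-variance dosage vector: ", paste(bad, collapse = ", "))
  }
  sweep(sweep(x, 2, mu, "-"), 2, sqrt(s2), "/")
}

#' Partition a gene's SNPs into LD blocks
#'
#' Greedy sequential rule over SNPs in position order: SNP k joins the
#' current block iff its r-squared with any SNP already in the block exceeds
#' `r2_threshold`; otherwise it opens a new block. Adjacent blocks are
#' therefore separated by SNP pairs with r-squared at or below the
#' threshold; full all-pairs cross-block independence is checked post hoc
#' and violations are recorded in the `cross_block_violations` attribute
#' (count of cross-block pairs above threshold), not repaired.
#'
#' Each block carries a moment estimate of its exchangeable correlation
#' (`rho`): the mean pairwise dosage correlation after aligning allele
#' coding to the block's first SNP, floored at 0. [fit_cov_structure()]
#' replaces it with the maximum-likelihood estimate.
#'
#' @param x dosage matrix for one gene, columns in position order.
#' @param r2_threshold blocks split where r-squared <= this value
#'   (default 0.05).
#' @return list of class `ld_partition`: `blocks` (list of integer column
#'   indices), `rho` (numeric per block), `n_snps`.
#' @export
build_ld_blocks <- function(x, r2_threshold = 0.05) {
  x <- as.matrix(x)
  p <- ncol(x)
  if (p < 1) stop("need at least one SNP")
  if (p == 1) {
    # single SNP: still reject zero variance for consistency
    .standardize_dosages(x)
    part <- list(blocks = list(1L), rho = 0, n_snps = 1L)
    class(part) <- "ld_partition"
    attr(part, "cross_block_violations") <- 0L
    return(part)
  }
  xs <- .standardize_dosages(x)
  cmat <- crossprod(xs) / nrow(xs)
  r2 <- cmat^2
  blocks <- list()
  current <- 1L
  for (k in 2:p) {
    if (any(r2[k, current] > r2_threshold)) {
      current <- c(current, k)
    } else {
      blocks[[length(blocks) + 1L]] <- current
      current <- k
    }
  }
  blocks[[length(blocks) + 1L]] <- current
  rho <- vapply(blocks, function(idx) {
    b <- length(idx)
    if (b == 1) return(0)
    sgn <- sign(cmat[idx[1], idx])
    sgn[sgn == 0] <- 1
    cb <- outer(sgn, sgn) * cmat[idx, idx]
    max(0, (sum(cb) - b) / (b * (b - 1)))
  }, numeric(1))
  viol <- 0L
  if (length(blocks) > 1) {
    bid <- integer(p)
    for (i in seq_along(blocks)) bid[blocks[[i]]] <- i
    cross <- outer(bid, bid, "!=") & upper.tri(r2)
    viol <- sum(r2[cross] > r2_threshold)
  }
  part <- list(blocks = blocks, rho = rho, n_snps = p)
  class(part) <- "ld_partition"
  attr(part, "cross_block_violations") <- viol
  part
}

# Gaussian log-likelihood of standardized columns under an exchangeable
# (compound-symmetry) correlation R(rho) restricted to one block, using
# t2 = sum of the block's correlation entries. For unit-diagonal S the
# likelihood depends on the data only through t2, and its maximizer over
# rho is the average pairwise correlation; see cs_rho_mle().
.cs_loglik <- function(rho, b, t2, n) {
  a <- 1 + (b - 1) * rho
  logdet <- log(a) + (b - 1) * log1p(-rho)
  trace <- (b - rho * t2 / a) / (1 - rho)
  -n / 2 * (b * log(2 * pi) + logdet + trace)
}

#' Maximum-likelihood exchangeable correlation for one block
#'
#' For dosage columns standardized to zero mean and unit (1/n) variance,
#' the Gaussian likelihood of the compound-symmetry correlation model over
#' rho in \[0, 0.999\] is maximized exactly by the average pairwise
#' correlation, clamped to the box; the 1-d search therefore has a closed
#' solution (verified against numerical optimization in the test suite).
#'
#' @param t2 sum of all entries of the block's correlation matrix.
#' @param b block size (number of SNPs).
#' @return rho-hat in \[0, 0.999\].
#' @export
cs_rho_mle <- function(t2, b) {
  if (b < 2) return(0)
  unname(min(max((t2 - b) / (b * (b - 1)), 0), 0.999))
}

#' Fit candidate covariance structures to a gene and select by AIC
#'
#' Evaluates the Gaussian log-likelihood of the standardized dosage columns
#' under three correlation models:
#'
#' * `IND` — identity (all SNPs independent), 0 parameters;
#' * `CS` — a single exchangeable correlation across all the gene's SNPs,
#'   1 parameter;
#' * `LD-CS` — exchangeable correlation within each LD block, zero across
#'   blocks; one parameter per block of size >= 2.
#'
#' Correlation parameters are estimated by maximum likelihood over
#' \[0, 0.999\] (closed-form solution, see [cs_rho_mle()]); allele coding
#' within a block is sign-aligned to the block's first SNP first. The
#' structure with minimal AIC (= 2k - 2 logLik) wins; ties go to the model
#' with fewer parameters in the order IND, CS, LD-CS.
#'
#' @param x dosage matrix for one gene (raw or standardized; columns are
#'   re-standardized internally, missing values mean-imputed).
#' @param partition an `ld_partition` from [build_ld_blocks()].
#' @return list with `fits` (data frame `structure`, `loglik`, `n_params`,
#'   `aic`), `selected` (structure name), and `partition` — the block
#'   partition carrying the fitted rho for the selected structure (IND:
#'   original blocks with rho 0; CS: one gene-wide block; LD-CS: original
#'   blocks with per-block ML rho), ready for [effective_gene_size()].
#' @export
fit_cov_structure <- function(x, partition) {
  stopifnot(inherits(partition, "ld_partition"))
  x <- as.matrix(x)
  p <- ncol(x)
  if (sum(lengths(partition$blocks)) != p || partition$n_snps != p) {
    stop("partition does not cover the gene's SNPs")
  }
  n <- nrow(x)
  bmax <- max(lengths(partition$blocks))
  if (n <= bmax) stop("need more samples than SNPs in the largest block")
  xs <- .standardize_dosages(x)
  cmat <- crossprod(xs) / n

  # Allele coding is arbitrary, so columns are sign-aligned once, within
  # their LD block (flip to correlate positively with the block's first
  # SNP); singletons are untouched. The same aligned correlation matrix
  # feeds every candidate so none can gain likelihood from per-candidate
  # coding choices.
  sgn <- rep(1, p)
  for (idx in partition$blocks) {
    if (length(idx) > 1) {
      s <- sign(cmat[idx[1], idx])
      s[s == 0] <- 1
      sgn[idx] <- s
    }
  }
  cmat <- outer(sgn, sgn) * cmat

  block_stats <- function(idx) {
    b <- length(idx)
    if (b == 1) return(c(b = 1, t2 = 1))
    c(b = b, t2 = sum(cmat[idx, idx]))
  }

  ll_ind <- -n / 2 * (p * log(2 * pi) + p)

  gs <- block_stats(seq_len(p))
  rho_cs <- cs_rho_mle(gs[["t2"]], p)
  ll_cs <- if (p >= 2) .cs_loglik(rho_cs, p, gs[["t2"]], n) else ll_ind
  k_cs <- if (p >= 2) 1L else 0L

  rho_ld <- numeric(length(partition$blocks))
  ll_ld <- 0
  k_ld <- 0L
  for (i in seq_along(partition$blocks)) {
    st <- block_stats(partition$blocks[[i]])
    rho_ld[i] <- cs_rho_mle(st[["t2"]], st[["b"]])
    ll_ld <- ll_ld + .cs_loglik(rho_ld[i], st[["b"]], st[["t2"]], n)
    if (st[["b"]] >= 2) k_ld <- k_ld + 1L
  }

  fits <- data.frame(
    structure = c("IND", "CS", "LD-CS"),
    loglik = c(ll_ind, ll_cs, ll_ld),
    n_params = c(0L, k_cs, k_ld),
    stringsAsFactors = FALSE
  )
  fits$aic <- 2 * fits$n_params - 2 * fits$loglik
  sel <- fits$structure[order(fits$aic, fits$n_params)][1]

  out_part <- switch(sel,
    "IND" = {
      part <- partition
      part$rho[] <- 0
      part
    },
    "CS" = {
      part <- list(blocks = list(seq_len(p)), rho = rho_cs, n_snps = p)
      class(part) <- "ld_partition"
      part
    },
    "LD-CS" = {
      part <- partition
      part$rho <- rho_ld
      part
    }
  )
  list(fits = fits, selected = sel, partition = out_part)
}

#' Effective gene size under a fitted LD-block partition
#'
#' LD-discounted number of independent SNPs in a gene, summed over blocks.
#' An exchangeable-correlation block of size b has correlation eigenvalues
#' `1 + (b-1) rho` (once) and `1 - rho` (b-1 times); the default
#' (`method = "galwey"`) scores the block with the eigenvalue-based
#' effective number of independent tests
#' \deqn{(\sum_j \sqrt{\lambda_j})^2 / \sum_j \lambda_j,}
#' which equals b at rho = 0, decreases monotonically in rho, tends to 1
#' as rho -> 1, and — crucially for calibrating a minimum-p-value summary —
#' has zero derivative at rho = 0, so sampling noise in small rho-hat does
#' not erode the size of large genes.
#'
#' `method = "design_effect"` scores each block as
#' `b / (1 + (b - 1) rho)` (the variance-inflation correction for a mean
#' of correlated terms); it shares the same limits but under-counts the
#' effective number of tests at intermediate rho. A custom strategy can be
#' plugged in as `formula(block_sizes, rhos)` returning per-block
#' contributions, without touching callers.
#'
#' @param partition an `ld_partition` whose `rho` entries lie in \[0, 1).
#' @param method `"galwey"` (default) or `"design_effect"`.
#' @param formula optional function `(b, rho) -> per-block contributions`,
#'   overriding `method`.
#' @return effective gene size, a float in \[number of blocks, gene size\].
#' @export
effective_gene_size <- function(partition,
                                method = c("galwey", "design_effect"),
                                formula = NULL) {
  stopifnot(inherits(partition, "ld_partition"))
  method <- match.arg(method)
  if (!length(partition$blocks)) stop("empty LD partition")
  b <- lengths(partition$blocks)
  rho <- partition$rho
  if (length(rho) != length(b)) stop("partition rho/blocks length mismatch")
  if (any(rho < 0 | rho >= 1)) stop("block rho must lie in [0, 1)")
  if (is.null(formula)) {
    formula <- switch(method,
      # eigenvalue trace of a correlation matrix is b
      galwey = function(b, rho) {
        (sqrt(1 + (b - 1) * rho) + (b - 1) * sqrt(1 - rho))^2 / b
      },
      design_effect = function(b, rho) b / (1 + (b - 1) * rho)
    )
  }
  sum(formula(b, rho))
}

#' Serialize LD-block partitions to TSV
#'
#' @param partitions named list of `ld_partition` objects (names = gene ids).
#' @param snp_ids named list of character vectors giving each gene's SNP ids
#'   in column order.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ld_blocks <- function(partitions, snp_ids, path) {
  rows <- lapply(names(partitions), function(gid) {
    part <- partitions[[gid]]
    do.call(rbind, lapply(seq_along(part$blocks), function(i) {
      data.frame(gene_id = gid, block_index = i,
                 snp_id = snp_ids[[gid]][part$blocks[[i]]],
                 rho_hat = part$rho[i], stringsAsFactors = FALSE)
    }))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
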