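#' LD-corrected scaled top-m gene-level measure
#'
#' Collapses a gene's SNP p-values to `(n_eff + 1) * mean(top-m p-values)`,
#' where `n_eff` is the effective gene size. With independent SNPs
#' (`n_eff` = gene size) and uniform p-values the m-th order statistic is
#' Beta(m, n - m + 1) with mean m / (n + 1), so the measure has expectation
#' (m + 1) / 2 irrespective of gene size — removing the size bias of raw
#' minimum p-values. Small values indicate association.
#'
#' Genes with fewer than `m` SNPs use all their p-values. P-values of
#' exactly 0 (upstream underflow) are clamped to the smallest positive
#' double with a warning.
#'
#' @param pvals the gene's SNP p-values, each in (0, 1\].
#' @param m number of smallest p-values averaged (>= 1).
#' @param n_eff effective gene size (see [effective_gene_size()]).
#' @return the gene-level measure, a positive float.
#' @export
prage_gene_measure <- function(pvals, m, n_eff) {
  pvals <- .check_pvals(pvals)
  if (!is.numeric(m) || length(m) != 1 || m < 1) stop("m must be a positive integer")
  top <- sort(pvals)[seq_len(min(m, length(pvals)))]
  (n_eff + 1) * mean(top)
}

#' Negative-log order-statistic gene measure (Z-method baseline)
#'
#' The uncorrected gene summary used by the PAGE-style Z-statistic method:
#' `-log(p_(m))`, the natural logarithm of the m-th smallest SNP p-value.
#' Genes with fewer than `m` SNPs fall back to their largest order
#' statistic with a warning. Large values indicate association; the
#' expectation grows with gene size (E\[p_(1)\] = 1/(n+1)), which is the
#' size bias the scaled measure removes.
#'
#' @inheritParams prage_gene_measure
#' @return `-log(p_(m))`, a non-negative float.
#' @export
zmethod_gene_measure <- function(pvals, m) {
  pvals <- .check_pvals(pvals)
  if (!is.numeric(m) || length(m) != 1 || m < 1) stop("m must be a positive integer")
  srt <- sort(pvals)
  if (length(srt) < m) {
    warning("gene has ", length(srt), " SNPs < m = ", m,
            "; using the largest available order statistic")
    m <- length(srt)
  }
  -log(srt[m])
}

.check_pvals <- function(pvals) {
  if (!length(pvals)) stop("empty p-value vector")
  if (anyNA(pvals)) stop("NA p-values")
  if (any(pvals > 1 | pvals < 0)) stop("p-values must lie in (0, 1]")
  if (any(pvals == 0)) {
    warning("p-value(s) of exactly 0 clamped to the smallest positive double")
    pvals[pvals == 0] <- .Machine$double.xmin
  }
  pvals
}

# Per-gene working table shared by summarize_genes() and the study loop:
# sorted p-values, LD partition, selected structure and effective size are
# computed once per gene so measures for several m come cheap.
.gene_tables <- function(g, assoc, map, r2_threshold = 0.05) {
  ok <- assoc$status_flag == "ok"
  pv <- stats::setNames(assoc$pvalue[ok], assoc$snp_id[ok])
  keep <- map$snp_id %in% names(pv)
  map <- map[keep, , drop = FALSE]
  gene_ids <- unique(map$gene_id)
  col_of <- match(map$snp_id, g$snp_meta$snp_id)
  split_cols <- split(col_of, map$gene_id)[gene_ids]
  out <- vector("list", length(gene_ids))
  names(out) <- gene_ids
  for (gid in gene_ids) {
    cols <- sort(split_cols[[gid]])  # position order within the gene
    x <- g$dosages[, cols, drop = FALSE]
    part <- build_ld_blocks(x, r2_threshold)
    fit <- fit_cov_structure(x, part)
    out[[gid]] <- list(
      snp_ids = g$snp_meta$snp_id[cols],
      pvals_sorted = sort(unname(pv[g$snp_meta$snp_id[cols]])),
      n_snps = length(cols),
      n_eff = effective_gene_size(fit$partition),
      structure = fit$selected,
      partition = fit$partition
    )
  }
  out
}

#' Per-gene summary table: effective sizes and gene-level measures
#'
#' Runs the full gene-level stage: groups post-QC SNP p-values by mapped
#' gene, partitions each gene's dosages into LD blocks, fits and selects a
#' covariance structure by AIC, computes the effective gene size, and
#' returns both the LD-corrected scaled top-m measure and the uncorrected
#' `-log p_(m)` baseline.
#'
#' @param g a [genotype_matrix()] (post-QC).
#' @param assoc per-SNP association results from [snp_logistic_scan()];
#'   only rows with `status_flag == "ok"` contribute.
#' @param map SNP-to-gene map data frame (`snp_id`, `gene_id`) from
#'   [map_snps_to_genes()].
#' @param m number of top p-values averaged per gene (default 1).
#' @param r2_threshold LD-block split threshold (default 0.05).
#' @return data frame with one row per gene: `gene_id`, `n_snps`, `n_eff`,
#'   `structure`, `measure`, `baseline_measure`, plus `top_pvals` as a
#'   comma-separated string of the m smallest p-values.
#' @export
summarize_genes <- function(g, assoc, map, m = 1, r2_threshold = 0.05) {
  tabs <- .gene_tables(g, assoc, map, r2_threshold)
  .summaries_from_tables(tabs, m)
}

.summaries_from_tables <- function(tabs, m) {
  gene_ids <- names(tabs)
  n <- length(gene_ids)
  out <- data.frame(
    gene_id = gene_ids,
    n_snps = vapply(tabs, `[[`, integer(1), "n_snps"),
    n_eff = vapply(tabs, `[[`, numeric(1), "n_eff"),
    structure = vapply(tabs, `[[`, character(1), "structure"),
    measure = numeric(n), baseline_measure = numeric(n),
    top_pvals = character(n),
    stringsAsFactors = FALSE, row.names = NULL
  )
  for (i in seq_len(n)) {
    tb <- tabs[[i]]
    mm <- min(m, length(tb$pvals_sorted))
    top <- tb$pvals_sorted[seq_len(mm)]
    out$measure[i] <- (tb$n_eff + 1) * mean(top)
    out$baseline_measure[i] <- -log(tb$pvals_sorted[mm])
    out$top_pvals[i] <- paste(signif(top, 6), collapse = ",")
  }
  out
}

#' Write the per-gene summary table to TSV
#'
#' @param gene_summary data frame from [summarize_genes()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gene_summary <- function(gene_summary, path) {
  utils::write.table(gene_summary, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
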