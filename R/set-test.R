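#' Heterogeneous-variance competitive gene-set test
#'
#' Tests each gene set against the complement of all other summarized genes
#' with a Welch-type two-sample statistic on the gene-level measures,
#' allowing each side its own variance:
#' \deqn{t_i = (\bar x_i - \bar x_c) / \sqrt{s_i^2/N_i + s_c^2/N_c}}
#' with Satterthwaite degrees of freedom
#' \deqn{df_i = (s_i^2/N_i + s_c^2/N_c)^2 /
#'   [(s_i^2/N_i)^2/(N_i-1) + (s_c^2/N_c)^2/(N_c-1)].}
#' Enrichment means smaller measures, so the default alternative is the
#' lower tail of the Student-t reference. Sets with fewer than
#' `min_set_size` genes are flagged and excluded from the q-value
#' computation (their q is `NA`); sets whose measured membership or
#' complement has fewer than 2 genes are skipped with an error record.
#'
#' @param gene_summary data frame with `gene_id` and the measure column
#'   (e.g. from [summarize_genes()]).
#' @param sets named list of character vectors (gene sets), e.g. from
#'   [read_gmt()].
#' @param min_set_size minimum genes per set for q-value inclusion
#'   (default 10, below which the normal approximation is unreliable).
#' @param alternative `"less"` (enrichment, default) or `"two.sided"`.
#' @param comparison `"complement"` (default): the comparison group is all
#'   summarized genes outside the set; `"global"`: the set mean is compared
#'   to the global mean with the set's own variance on both terms.
#' @param measure_col column of `gene_summary` holding the measure.
#' @return data frame with one row per set: `set_id`, `n_genes`,
#'   `mean_measure`, `var_measure`, `statistic`, `df`, `pvalue`, `qvalue`,
#'   `flagged_small`, `error`.
#' @export
prage_set_test <- function(gene_summary, sets, min_set_size = 10,
                           alternative = c("less", "two.sided"),
                           comparison = c("complement", "global"),
                           measure_col = "measure") {
  alternative <- match.arg(alternative)
  comparison <- match.arg(comparison)
  measures <- stats::setNames(gene_summary[[measure_col]], gene_summary$gene_id)
  if (anyNA(measures) || any(!is.finite(measures))) {
    stop("gene measures must be finite and non-missing")
  }
  res <- data.frame(
    set_id = names(sets), n_genes = NA_integer_, mean_measure = NA_real_,
    var_measure = NA_real_, statistic = NA_real_, df = NA_real_,
    pvalue = NA_real_, qvalue = NA_real_,
    flagged_small = FALSE, error = NA_character_,
    stringsAsFactors = FALSE
  )
  all_genes <- names(measures)
  for (i in seq_along(sets)) {
    members <- intersect(unique(sets[[i]]), all_genes)
    xi <- measures[members]
    ni <- length(xi)
    res$n_genes[i] <- ni
    res$flagged_small[i] <- ni < min_set_size
    if (comparison == "complement") {
      xc <- measures[setdiff(all_genes, members)]
    } else {
      xc <- measures
    }
    nc <- length(xc)
    if (ni < 2 || nc < 2) {
      res$error[i] <- "fewer than 2 genes in set or comparison group"
      next
    }
    si2 <- stats::var(xi)
    sc2 <- stats::var(xc)
    res$mean_measure[i] <- mean(xi)
    res$var_measure[i] <- si2
    se2 <- si2 / ni + sc2 / nc
    if (se2 <= 0) {
      res$error[i] <- "zero pooled variance"
      next
    }
    tt <- (mean(xi) - mean(xc)) / sqrt(se2)
    df <- se2^2 / ((si2 / ni)^2 / (ni - 1) + (sc2 / nc)^2 / (nc - 1))
    res$statistic[i] <- tt
    res$df[i] <- df
    res$pvalue[i] <- if (alternative == "less") {
      stats::pt(tt, df)
    } else {
      2 * stats::pt(-abs(tt), df)
    }
    res$pvalue[i] <- min(max(res$pvalue[i], .Machine$double.xmin), 1)
  }
  eligible <- !res$flagged_small & is.na(res$error)
  if (any(eligible)) res$qvalue[eligible] <- qvalues(res$pvalue[eligible])
  res
}

#' PAGE-style Z-statistic gene-set test (baseline)
#'
#' Standardizes each set's mean gene measure against the mean and SD of the
#' measures over all summarized genes:
#' \deqn{Z_i = (\bar x_i - \mu) \sqrt{N_i} / \sigma,}
#' with an upper-tail normal p-value (the baseline measure `-log p_(m)` is
#' large under enrichment). No LD or gene-size correction is applied — this
#' is the comparison method whose level degrades with gene size.
#'
#' @param gene_summary data frame with `gene_id` and the baseline measure.
#' @param sets named list of character vectors.
#' @param min_set_size sets below this size are flagged and excluded from
#'   q-values (default 10).
#' @param measure_col column holding the baseline measure.
#' @return data frame as in [prage_set_test()] (no `df` column content).
#' @export
zmethod_set_test <- function(gene_summary, sets, min_set_size = 10,
                             measure_col = "baseline_measure") {
  measures <- stats::setNames(gene_summary[[measure_col]], gene_summary$gene_id)
  if (anyNA(measures) || any(!is.finite(measures))) {
    stop("gene measures must be finite and non-missing")
  }
  if (length(measures) < 2) stop("need at least 2 summarized genes")
  mu <- mean(measures)
  sigma <- stats::sd(measures)
  if (sigma == 0) stop("zero variance across gene measures")
  res <- data.frame(
    set_id = names(sets), n_genes = NA_integer_, mean_measure = NA_real_,
    var_measure = NA_real_, statistic = NA_real_, df = NA_real_,
    pvalue = NA_real_, qvalue = NA_real_, flagged_small = FALSE,
    error = NA_character_, stringsAsFactors = FALSE
  )
  for (i in seq_along(sets)) {
    members <- intersect(unique(sets[[i]]), names(measures))
    ni <- length(members)
    res$n_genes[i] <- ni
    res$flagged_small[i] <- ni < min_set_size
    if (ni < 1) {
      res$error[i] <- "no measured genes in set"
      next
    }
    xi <- measures[members]
    res$mean_measure[i] <- mean(xi)
    res$var_measure[i] <- if (ni > 1) stats::var(xi) else NA_real_
    z <- (mean(xi) - mu) * sqrt(ni) / sigma
    res$statistic[i] <- z
    res$pvalue[i] <- min(max(stats::pnorm(z, lower.tail = FALSE),
                             .Machine$double.xmin), 1)
  }
  eligible <- !res$flagged_small & is.na(res$error)
  if (any(eligible)) res$qvalue[eligible] <- qvalues(res$pvalue[eligible])
  res
}

#' Storey q-values
#'
#' False-discovery-rate q-values with the null proportion estimated as
#' `pi0 = #\{p > lambda\} / ((1 - lambda) n)` at `lambda = 0.5`, capped at 1.
#' `q_i = min over p_j >= p_i of pi0 * n * p_j / rank(p_j)`; ties share the
#' maximal rank so equal p-values get equal q-values. Forcing `pi0 = 1`
#' reproduces the Benjamini-Hochberg step-up adjustment.
#'
#' @param pvals p-values in (0, 1].
#' @param lambda tuning point for the pi0 estimate (default 0.5).
#' @param pi0 optional override of the estimated null proportion.
#' @return q-values, same length and order as `pvals`.
#' @export
qvalues <- function(pvals, lambda = 0.5, pi0 = NULL) {
  if (!length(pvals)) return(numeric(0))
  if (any(is.na(pvals)) || any(pvals <= 0) || any(pvals > 1)) {
    stop("p-values must lie in (0, 1]")
  }
  n <- length(pvals)
  if (is.null(pi0)) pi0 <- min(1, sum(pvals > lambda) / ((1 - lambda) * n))
  r <- rank(pvals, ties.method = "max")
  ord <- order(pvals, decreasing = TRUE)
  q <- numeric(n)
  running <- Inf
  for (i in ord) {
    running <- min(running, pi0 * n * pvals[i] / r[i])
    q[i] <- running
  }
  pmin(q, 1)
}

#' Normality diagnostic for the null set-level statistic
#'
#' Assesses how well the set statistic's Student-t reference holds at small
#' set sizes: for each size, draws `n_draws` random gene subsets from the
#' supplied measures (a global-null resampling), computes the
#' heterogeneous-variance set statistic of each subset against its
#' complement, and reports a Shapiro-Wilk normality p-value plus QQ data.
#' With right-skewed measures, small sets (around 5 genes) fail the normal
#' approximation while sizes 10-20 pass — the basis for the recommended
#' minimum set size of 10.
#'
#' @param measures numeric vector of gene-level measures (named or not).
#' @param set_sizes subset sizes to probe (default `c(5, 10, 20)`).
#' @param n_draws random subsets per size (>= 100).
#' @param seed optional RNG seed.
#' @return named list (one element per size) with `statistics`,
#'   `shapiro_p`, and `qq` (data frame `theoretical`, `sample`).
#' @export
normality_diagnostic <- function(measures, set_sizes = c(5, 10, 20),
                                 n_draws = 500, seed = NULL) {
  if (n_draws < 100) stop("n_draws must be at least 100")
  if (stats::sd(measures) == 0) stop("degenerate (constant) gene measures")
  if (max(set_sizes) >= length(measures)) {
    stop("set size exceeds the number of available genes")
  }
  if (!is.null(seed)) set.seed(seed)
  out <- list()
  for (s in set_sizes) {
    stat <- numeric(n_draws)
    for (d in seq_len(n_draws)) {
      idx <- sample.int(length(measures), s)
      xi <- measures[idx]
      xc <- measures[-idx]
      se2 <- stats::var(xi) / s + stats::var(xc) / length(xc)
      stat[d] <- (mean(xi) - mean(xc)) / sqrt(se2)
    }
    sw <- stats::shapiro.test(if (n_draws > 5000) sample(stat, 5000) else stat)
    z <- sort((stat - mean(stat)) / stats::sd(stat))
    out[[as.character(s)]] <- list(
      statistics = stat,
      shapiro_p = sw$p.value,
      qq = data.frame(theoretical = stats::qnorm(stats::ppoints(n_draws)),
                      sample = z)
    )
  }
  out
}

#' Write set-level results to TSV, sorted by q-value
#'
#' @param set_results data frame from [prage_set_test()] or
#'   [zmethod_set_test()].
#' @param path output file.
#' @param n_snps_per_set optional named vector adding an `n_snps` column.
#' @return `path`, invisibly.
#' @export
write_set_results <- function(set_results, path, n_snps_per_set = NULL) {
  out <- set_results
  if (!is.null(n_snps_per_set)) {
    out$n_snps <- as.integer(n_snps_per_set[out$set_id])
    out <- out[, c("set_id", "n_genes", "n_snps",
                   setdiff(names(out), c("set_id", "n_genes", "n_snps")))]
  }
  out <- out[order(out$qvalue, out$pvalue), , drop = FALSE]
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
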