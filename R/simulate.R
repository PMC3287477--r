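#' Simulation design for the size/power study
#'
#' Encodes the synthetic GWA design used throughout the package's
#' validation: 5 gene sets of 20 genes whose per-gene SNP counts span five
#' size ranges (9-12, 12-20, 20-30, 26-40, 36-49 SNPs), 500 individuals,
#' one causal SNP (MAF 0.2) in each of 5 causal genes of a designated
#' causal set, and a per-allele log-odds effect of 0, 0.3 or 0.6.
#' Genotypes carry block LD from a Gaussian-copula model: latent
#' multivariate normal with exchangeable within-block correlation drawn
#' from `rho_range`, thresholded to Hardy-Weinberg genotype frequencies at
#' each SNP's MAF.
#'
#' @param n_individuals samples per dataset (default 500).
#' @param genes_per_set genes per set (default 20).
#' @param gene_size_ranges list of c(min, max) SNP counts, one per set.
#' @param causal_set_index which set carries the causal genes (default 1).
#' @param n_causal_genes causal genes within the causal set (default 5).
#' @param causal_maf minor allele frequency of each causal SNP (default 0.2).
#' @param beta per-allele log odds ratio of each causal SNP (default 0).
#' @param intercept_mode `"prevalence_0.5"` (intercept solved so the
#'   expected case fraction is 0.5) or `"fixed"` (intercept 0).
#' @param block_size_range LD-block sizes in SNPs (default 3-8).
#' @param rho_range within-block latent correlation range (default 0.4-0.8).
#' @param maf_range MAF range of non-causal SNPs (default 0.05-0.5).
#' @param seed RNG seed (default 1).
#' @return a list of class `simulation_config`.
#' @export
simulation_config <- function(n_individuals = 500,
                              genes_per_set = 20,
                              gene_size_ranges = list(c(9, 12), c(12, 20),
                                                      c(20, 30), c(26, 40),
                                                      c(36, 49)),
                              causal_set_index = 1,
                              n_causal_genes = 5,
                              causal_maf = 0.2,
                              beta = 0,
                              intercept_mode = c("prevalence_0.5", "fixed"),
                              block_size_range = c(3, 8),
                              rho_range = c(0.4, 0.8),
                              maf_range = c(0.05, 0.5),
                              seed = 1) {
  intercept_mode <- match.arg(intercept_mode)
  stopifnot(n_individuals >= 10, genes_per_set >= 1,
            length(gene_size_ranges) >= 1,
            causal_set_index >= 1, causal_set_index <= length(gene_size_ranges),
            n_causal_genes >= 1, n_causal_genes <= genes_per_set,
            causal_maf > 0, causal_maf < 1, beta >= 0)
  if (any(unlist(rho_range) < 0) || any(unlist(rho_range) >= 1)) {
    stop("rho_range must lie in [0, 1)")
  }
  structure(
    list(n_individuals = n_individuals, genes_per_set = genes_per_set,
         gene_size_ranges = gene_size_ranges,
         causal_set_index = causal_set_index,
         n_causal_genes = n_causal_genes, causal_maf = causal_maf,
         beta = beta, intercept_mode = intercept_mode,
         block_size_range = block_size_range, rho_range = rho_range,
         maf_range = maf_range, seed = seed),
    class = "simulation_config"
  )
}

#' Simulate block-LD genotypes with annotations
#'
#' Per gene, the SNP count is drawn uniformly from its set's size range and
#' SNPs are split into consecutive blocks whose sizes come from
#' `block_size_range`. Each block's genotypes arise from a latent
#' exchangeable-correlation normal (correlation drawn from `rho_range`)
#' thresholded per SNP at the Hardy-Weinberg genotype frequencies of its
#' MAF. Genes are laid out on one synthetic chromosome with 2 Mb spacing
#' so the 500 kb nearest-gene rule maps every SNP to its own gene
#' unambiguously. One causal SNP (MAF `causal_maf`) is planted in each of
#' `n_causal_genes` randomly chosen genes of the causal set.
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes` ([genotype_matrix()]), `genes` (annotation
#'   data frame), `sets` (named list), and `truth` (causal set, gene and
#'   SNP ids, with block/rho layout per gene).
#' @export
simulate_genotypes <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)
  n <- config$n_individuals
  n_sets <- length(config$gene_size_ranges)
  sample_ids <- sprintf("ind%04d", seq_len(n))

  set_ids <- paste0("S", seq_len(n_sets))
  gene_count <- n_sets * config$genes_per_set
  gene_ids <- sprintf("g%03d", seq_len(gene_count))
  gene_set <- rep(set_ids, each = config$genes_per_set)
  sets <- split(gene_ids, gene_set)[set_ids]

  causal_set <- set_ids[config$causal_set_index]
  causal_genes <- sort(sample(sets[[causal_set]], config$n_causal_genes))

  sizes <- integer(gene_count)
  for (i in seq_len(gene_count)) {
    rng <- config$gene_size_ranges[[match(gene_set[i], set_ids)]]
    sizes[i] <- sample(seq(rng[1], rng[2]), 1)
  }
  total_snps <- sum(sizes)

  dos <- matrix(0, n, total_snps)
  snp_id <- character(total_snps)
  snp_pos <- integer(total_snps)
  genes <- data.frame(gene_id = gene_ids, chrom = "1",
                      start = NA_integer_, end = NA_integer_,
                      stringsAsFactors = FALSE)
  causal_snps <- character(0)
  layout <- vector("list", gene_count)
  names(layout) <- gene_ids

  col <- 0L
  for (i in seq_len(gene_count)) {
    p <- sizes[i]
    base <- (i - 1L) * 2000000L + 1000000L
    cols <- col + seq_len(p)
    snp_id[cols] <- sprintf("snp%05d", cols)
    snp_pos[cols] <- base + (seq_len(p) - 1L) * 1000L
    genes$start[i] <- base
    genes$end[i] <- base + (p - 1L) * 1000L

    bsizes <- integer(0)
    left <- p
    while (left > 0) {
      b <- sample(seq(config$block_size_range[1], config$block_size_range[2]), 1)
      b <- min(b, left)
      bsizes <- c(bsizes, b)
      left <- left - b
    }
    rhos <- stats::runif(length(bsizes), config$rho_range[1], config$rho_range[2])
    mafs <- stats::runif(p, config$maf_range[1], config$maf_range[2])

    causal_here <- gene_ids[i] %in% causal_genes
    if (causal_here) {
      csnp_local <- sample.int(p, 1)
      mafs[csnp_local] <- config$causal_maf
      causal_snps <- c(causal_snps, snp_id[cols[csnp_local]])
    }

    off <- 0L
    for (k in seq_along(bsizes)) {
      b <- bsizes[k]
      rho <- rhos[k]
      z0 <- stats::rnorm(n)
      lat <- sqrt(rho) * z0 + sqrt(1 - rho) *
        matrix(stats::rnorm(n * b), n, b)
      jcols <- cols[off + seq_len(b)]
      pj <- mafs[off + seq_len(b)]
      # HWE thresholds on the latent normal: P(0)=(1-p)^2, P(1)=2p(1-p)
      c1 <- stats::qnorm((1 - pj)^2)
      c2 <- stats::qnorm((1 - pj)^2 + 2 * pj * (1 - pj))
      dos[, jcols] <- (lat > rep(c1, each = n)) + (lat > rep(c2, each = n))
      off <- off + b
    }
    layout[[i]] <- list(block_sizes = bsizes, rho = rhos, maf = mafs)
    col <- col + p
  }

  # columns are generated in position order on one chromosome, so the
  # container invariants hold by construction
  g <- .genotype_matrix_unsafe(dos, data.frame(snp_id = snp_id, chrom = "1",
                                               pos = snp_pos,
                                               stringsAsFactors = FALSE),
                               sample_ids)
  list(
    genotypes = g, genes = genes, sets = sets,
    truth = list(causal_set = causal_set, causal_genes = causal_genes,
                 causal_snps = causal_snps, layout = layout)
  )
}

#' Simulate case/control status from causal dosages
#'
#' Disease model: `P(case | g) = plogis(b0 + beta * sum_j dosage_j)` over
#' the causal SNPs. In `prevalence_0.5` mode the intercept is solved
#' numerically so the expected case fraction over the realized genotypes
#' is 0.5; `fixed` mode uses intercept 0.
#'
#' @param genotypes a [genotype_matrix()].
#' @param truth truth list naming `causal_snps` (from
#'   [simulate_genotypes()]).
#' @param beta per-allele log odds ratio (>= 0).
#' @param intercept_mode see [simulation_config()].
#' @param seed RNG seed for the Bernoulli draws.
#' @return phenotype data frame (`sample_id`, `status`).
#' @export
simulate_phenotype <- function(genotypes, truth, beta,
                               intercept_mode = c("prevalence_0.5", "fixed"),
                               seed = NULL) {
  intercept_mode <- match.arg(intercept_mode)
  if (!is.null(seed)) set.seed(seed)
  if (beta > 0) {
    idx <- match(truth$causal_snps, genotypes$snp_meta$snp_id)
    if (anyNA(idx)) stop("causal SNPs missing from the genotype matrix")
    eta <- beta * rowSums(genotypes$dosages[, idx, drop = FALSE])
    if (stats::var(eta) == 0) stop("no variation in the causal linear predictor")
  } else {
    eta <- rep(0, length(genotypes$sample_ids))
  }
  b0 <- 0
  if (intercept_mode == "prevalence_0.5" && beta > 0) {
    b0 <- stats::uniroot(function(b) mean(stats::plogis(b + eta)) - 0.5,
                         c(-50, 50))$root
  }
  status <- stats::rbinom(length(eta), 1, stats::plogis(b0 + eta))
  data.frame(sample_id = genotypes$sample_ids, status = status,
             stringsAsFactors = FALSE)
}

#' Simulate a complete dataset (genotypes + phenotype + truth)
#'
#' @param config a [simulation_config()].
#' @return list with `genotypes`, `phenotype`, `genes`, `sets`, `truth`.
#' @export
simulate_dataset <- function(config) {
  sim <- simulate_genotypes(config)
  sim$phenotype <- simulate_phenotype(sim$genotypes, sim$truth, config$beta,
                                      config$intercept_mode)
  sim
}

# Deterministic per-replicate seed below 2^31, Knuth-style mix of the
# master seed and replicate index.
.replicate_seed <- function(master_seed, r) {
  as.integer((as.numeric(master_seed) * 48271 + as.numeric(r) * 69621) %%
               2147483563)
}

#' Empirical size/power study of the set-level tests
#'
#' Runs `n_reps` independent replicates of the full pipeline (simulate ->
#' QC -> score-test scan -> 500 kb gene mapping -> LD blocks / effective
#' size -> gene measures -> set tests) and tabulates, for every set, method,
#' top-m choice and significance level, the fraction of replicates in which
#' the set's p-value fell below the level. At `beta = 0` that fraction is
#' the empirical type-I error of the designated causal set (and of every
#' other set); at `beta > 0` the causal set's row is the empirical power.
#'
#' @param config a [simulation_config()]; its `beta` and `causal_set_index`
#'   define the scenario. The per-replicate seed is derived from
#'   `config$seed` and the replicate index, so any replicate can be
#'   reproduced in isolation.
#' @param n_reps number of replicates (>= 50).
#' @param methods subset of `c("prage", "zmethod")`.
#' @param m_values top-m grid for the gene measures (default 1).
#' @param alphas significance levels (default 0.05 and 0.01).
#' @param min_set_size passed to the set tests (default 10).
#' @param verbose print a progress line every 100 replicates.
#' @return data frame: `set_id`, `gene_size_min`, `gene_size_max`,
#'   `causal`, `method`, `m`, `alpha`, `beta`, `n_reps`, `n_used`,
#'   `rejections`, `rate`, `mc_se`, plus attribute `n_failed` counting
#'   replicates excluded for QC/association failures.
#' @export
run_size_power_study <- function(config, n_reps, methods = c("prage", "zmethod"),
                                 m_values = 1, alphas = c(0.05, 0.01),
                                 min_set_size = 10, verbose = FALSE) {
  stopifnot(inherits(config, "simulation_config"))
  if (n_reps < 50) stop("n_reps must be at least 50")
  if (!length(methods)) stop("methods must name at least one of prage, zmethod")
  methods <- match.arg(methods, c("prage", "zmethod"), several.ok = TRUE)

  n_sets <- length(config$gene_size_ranges)
  set_ids <- paste0("S", seq_len(n_sets))
  grid <- expand.grid(set_id = set_ids, method = methods, m = m_values,
                      alpha = alphas, stringsAsFactors = FALSE)
  rej <- numeric(nrow(grid))
  used <- 0L
  failed <- 0L

  for (r in seq_len(n_reps)) {
    cfg_r <- config
    cfg_r$seed <- .replicate_seed(config$seed, r)
    pv <- tryCatch(.replicate_pvalues(cfg_r, methods, m_values, min_set_size),
                   error = function(e) e)
    if (inherits(pv, "error")) {
      failed <- failed + 1L
      next
    }
    used <- used + 1L
    key <- paste(grid$set_id, grid$method, grid$m)
    rej <- rej + as.numeric(pv[key] < grid$alpha)
    if (verbose && r %% 100 == 0) {
      message("replicate ", r, "/", n_reps)
    }
  }
  if (!used) stop("all replicates failed")

  sizes <- do.call(rbind, config$gene_size_ranges)
  out <- data.frame(
    set_id = grid$set_id,
    gene_size_min = sizes[match(grid$set_id, set_ids), 1],
    gene_size_max = sizes[match(grid$set_id, set_ids), 2],
    causal = grid$set_id == set_ids[config$causal_set_index],
    method = grid$method, m = grid$m, alpha = grid$alpha,
    beta = config$beta, n_reps = n_reps, n_used = used,
    rejections = rej, rate = rej / used,
    mc_se = sqrt(pmax(rej / used * (1 - rej / used), 0) / used),
    stringsAsFactors = FALSE
  )
  attr(out, "n_failed") <- failed
  out
}

# One replicate of the full pipeline; returns named p-values
# "<set> <method> <m>".
.replicate_pvalues <- function(config, methods, m_values, min_set_size) {
  sim <- simulate_dataset(config)
  qc <- qc_filter(sim$genotypes, phenotype = sim$phenotype)
  assoc <- snp_logistic_scan(qc$genotypes, sim$phenotype, fast = TRUE)
  mp <- map_snps_to_genes(qc$genotypes$snp_meta, sim$genes)
  tabs <- .gene_tables(qc$genotypes, assoc, mp$map)
  out <- numeric(0)
  for (m in m_values) {
    gs <- .summaries_from_tables(tabs, m)
    if ("prage" %in% methods) {
      res <- prage_set_test(gs, sim$sets, min_set_size = min_set_size)
      out[paste(res$set_id, "prage", m)] <- res$pvalue
    }
    if ("zmethod" %in% methods) {
      res <- zmethod_set_test(gs, sim$sets, min_set_size = min_set_size)
      out[paste(res$set_id, "zmethod", m)] <- res$pvalue
    }
  }
  out
}

#' Write a size/power study table to TSV
#'
#' @param study data frame from [run_size_power_study()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_study_table <- function(study, path) {
  utils::write.table(study, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
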