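#' Assemble a pipeline run configuration
#'
#' Collects input paths and analysis parameters for [run_pipeline()].
#' Defaults: top-m = 1, 500 kb mapping window, r-squared block threshold
#' 0.05, minimum set size 10, QC at MAF 0.01 / missingness 0.05 /
#' HWE 1e-6.
#'
#' @param genotype_file dosage TSV (or .raw, detected by extension).
#' @param phenotype_file phenotype/covariate TSV.
#' @param snp_map_file SNP map TSV (or .bim, detected by extension).
#' @param gene_file gene annotation BED (or .tsv dialect, by extension).
#' @param gmt_file gene-set GMT.
#' @param out_dir output directory (created if absent).
#' @param m top-m p-values averaged per gene.
#' @param window_bp SNP-to-gene mapping window.
#' @param r2_threshold LD-block split threshold.
#' @param min_set_size minimum genes per tested set.
#' @param maf_min,miss_max,hwe_alpha QC thresholds.
#' @param alternative set-test alternative (`"less"` or `"two.sided"`).
#' @param fast_scan use the score-test scan (`TRUE`) or per-SNP logistic
#'   regression with covariates (`FALSE`).
#' @param seed recorded in the manifest (the pipeline itself is
#'   deterministic given its inputs).
#' @return list of class `run_config`.
#' @export
run_config <- function(genotype_file, phenotype_file, snp_map_file,
                       gene_file, gmt_file, out_dir,
                       m = 1, window_bp = 500000, r2_threshold = 0.05,
                       min_set_size = 10, maf_min = 0.01, miss_max = 0.05,
                       hwe_alpha = 1e-6, alternative = "less",
                       fast_scan = TRUE, seed = 1) {
  cfg <- as.list(environment())
  class(cfg) <- "run_config"
  cfg
}

#' Run the full enrichment pipeline
#'
#' QC -> additive association scan -> 500 kb nearest-gene mapping -> LD
#' blocks, covariance selection and effective gene sizes -> gene-level
#' measures -> set-level tests (LD-corrected Welch test and Z-statistic
#' baseline) -> q-values. Writes per-SNP, per-gene and per-set TSVs plus a
#' JSON manifest with stage counts, parameter values and a config hash;
#' the run is deterministic given the config. Inputs are checked up front
#' so a missing file fails before any output is written.
#'
#' @param config a [run_config()].
#' @return (invisibly) list with `snp_results`, `gene_summary`,
#'   `prage_sets`, `zmethod_sets`, `manifest`.
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "run_config"))
  files <- c(genotype = config$genotype_file, phenotype = config$phenotype_file,
             snp_map = config$snp_map_file, gene = config$gene_file,
             gmt = config$gmt_file)
  missing_files <- files[!file.exists(files)]
  if (length(missing_files)) {
    stop("missing input file(s): ",
         paste(names(missing_files), "=", missing_files, collapse = ", "))
  }
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop("pipeline stage '", name, "' failed: ", conditionMessage(e),
           call. = FALSE)
    })
  }

  snp_map <- stage("read_snp_map", {
    if (grepl("\\.bim$", config$snp_map_file)) read_bim(config$snp_map_file)
    else read_snp_map(config$snp_map_file)
  })
  g <- stage("read_genotypes", {
    if (grepl("\\.raw$", config$genotype_file)) {
      read_genotype_raw(config$genotype_file, snp_map)
    } else {
      read_genotype_tsv(config$genotype_file, snp_map)
    }
  })
  ph <- stage("read_phenotype",
              read_phenotype_tsv(config$phenotype_file, g$sample_ids))
  genes <- stage("read_genes", {
    if (grepl("\\.bed$", config$gene_file)) read_bed_genes(config$gene_file)
    else read_gene_tsv(config$gene_file)
  })
  sets <- stage("read_gmt", read_gmt(config$gmt_file))

  n_snps_in <- nrow(g$snp_meta)
  qc <- stage("qc", qc_filter(g, config$maf_min, config$miss_max,
                              config$hwe_alpha, phenotype = ph))
  assoc <- stage("assoc",
                 snp_logistic_scan(qc$genotypes, ph, fast = config$fast_scan))
  mp <- stage("map", map_snps_to_genes(qc$genotypes$snp_meta, genes,
                                       config$window_bp))
  gs <- stage("summarize", summarize_genes(qc$genotypes, assoc, mp$map,
                                           m = config$m,
                                           r2_threshold = config$r2_threshold))
  prage_res <- stage("settest",
                     prage_set_test(gs, sets, min_set_size = config$min_set_size,
                                    alternative = config$alternative))
  z_res <- stage("settest", zmethod_set_test(gs, sets,
                                             min_set_size = config$min_set_size))

  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  outp <- function(f) file.path(config$out_dir, f)
  write_snp_results(assoc, outp("snp_results.tsv"))
  utils::write.table(qc$exclusions, outp("qc_exclusions.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  write_gene_summary(gs, outp("gene_summary.tsv"))
  snp_per_set <- vapply(sets, function(members) {
    sum(mp$map$gene_id %in% members)
  }, integer(1))
  write_set_results(prage_res, outp("set_results_prage.tsv"), snp_per_set)
  write_set_results(z_res, outp("set_results_zmethod.tsv"), snp_per_set)

  cfg_flat <- unlist(lapply(unclass(config), as.character))
  writeLines(paste0(names(cfg_flat), "=", cfg_flat), outp("config.txt"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("prage")),
    config = as.list(cfg_flat),
    config_hash = sprintf("%08x",
      sum(utf8ToInt(paste(names(cfg_flat), cfg_flat, collapse = ";")) *
            seq_along(utf8ToInt(paste(names(cfg_flat), cfg_flat,
                                      collapse = ";")))) %% 4294967296),
    counts = list(
      snps_in = n_snps_in,
      snps_post_qc = nrow(qc$genotypes$snp_meta),
      snps_mapped = nrow(mp$map),
      snps_unmapped = length(mp$unmapped),
      genes_summarized = nrow(gs),
      sets_tested = sum(is.na(prage_res$error)),
      sets_flagged_small = sum(prage_res$flagged_small)
    ),
    warnings = list(
      qc_exclusions = nrow(qc$exclusions),
      unmapped_snps = length(mp$unmapped),
      small_sets = sum(prage_res$flagged_small)
    )
  )
  jsonlite::write_json(manifest, outp("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(list(snp_results = assoc, gene_summary = gs,
                 prage_sets = prage_res, zmethod_sets = z_res,
                 manifest = manifest))
}

#' Generate an on-disk synthetic dataset
#'
#' Writes a complete, mutually consistent input bundle produced by the
#' simulator: genotype TSV and .raw, phenotype TSV, SNP map TSV, gene BED,
#' set GMT and a truth JSON. `scale = "tiny"` (50 samples, 2 sets x 5 genes
#' of 3-6 SNPs) is for fast unit tests; `scale = "paper"` is the full
#' benchmark design (5 sets of 20 genes, sizes 9-49 SNPs, 500 samples)
#' used for the simulation study.
#'
#' @param scale `"tiny"` or `"paper"`.
#' @param dir output directory (created if absent).
#' @param seed RNG seed.
#' @param beta causal effect size (default 0).
#' @return named character vector of the file paths written.
#' @export
fixture_generator <- function(scale = c("tiny", "paper"), dir, seed = 1,
                              beta = 0) {
  scale <- match.arg(scale)
  cfg <- if (scale == "tiny") {
    simulation_config(n_individuals = 50, genes_per_set = 5,
                      gene_size_ranges = list(c(3, 6), c(4, 8)),
                      causal_set_index = 1, n_causal_genes = 2,
                      beta = beta, seed = seed)
  } else {
    simulation_config(beta = beta, seed = seed)
  }
  sim <- simulate_dataset(cfg)
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  paths <- c(
    genotype = file.path(dir, "genotypes.tsv"),
    genotype_raw = file.path(dir, "genotypes.raw"),
    phenotype = file.path(dir, "phenotype.tsv"),
    snp_map = file.path(dir, "snp_map.tsv"),
    genes = file.path(dir, "genes.bed"),
    gmt = file.path(dir, "sets.gmt"),
    truth = file.path(dir, "truth.json")
  )
  write_genotype_tsv(sim$genotypes, paths["genotype"])
  write_genotype_raw(sim$genotypes, paths["genotype_raw"], sim$phenotype)
  utils::write.table(sim$phenotype, paths["phenotype"], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(
    data.frame(chrom = sim$genotypes$snp_meta$chrom,
               snp_id = sim$genotypes$snp_meta$snp_id,
               pos = sim$genotypes$snp_meta$pos),
    paths["snp_map"], sep = "\t", quote = FALSE, row.names = FALSE)
  write_bed_genes(sim$genes, paths["genes"])
  write_gmt(sim$sets, paths["gmt"])
  jsonlite::write_json(sim$truth[c("causal_set", "causal_genes", "causal_snps")],
                       paths["truth"], auto_unbox = TRUE)
  paths
}
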