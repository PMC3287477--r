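# Shared fixture builders: everything is generated in code at test time.

# Genotype matrix with given dosage columns (list of vectors) on one
# chromosome, positions 1000 apart.
make_geno <- function(cols, chrom = "1", start = 1000L, step = 1000L) {
  dos <- do.call(cbind, cols)
  p <- ncol(dos)
  genotype_matrix(
    dos,
    data.frame(snp_id = sprintf("s%02d", seq_len(p)), chrom = chrom,
               pos = start + step * (seq_len(p) - 1L)),
    sample_ids = sprintf("i%03d", seq_len(nrow(dos)))
  )
}

# Random HWE dosages at a given MAF.
rand_dosage <- function(n, maf) {
  stats::rbinom(n, 2, maf)
}

# Dosage columns from a latent exchangeable-normal block thresholded to
# HWE frequencies (same construction as the simulator, independent code).
cs_block_dosages <- function(n, b, rho, maf) {
  z0 <- stats::rnorm(n)
  lat <- sqrt(rho) * z0 + sqrt(1 - rho) * matrix(stats::rnorm(n * b), n, b)
  c1 <- stats::qnorm((1 - maf)^2)
  c2 <- stats::qnorm((1 - maf)^2 + 2 * maf * (1 - maf))
  (lat > c1) + (lat > c2)
}

# Phenotype table for a genotype matrix.
make_pheno <- function(g, status, ...) {
  data.frame(sample_id = g$sample_ids, status = status, ...,
             stringsAsFactors = FALSE)
}

# Near-duplicate of a dosage vector: k entries resampled.
flip <- function(v, k, maf = 0.3) {
  i <- sample(seq_along(v), k)
  v[i] <- rand_dosage(k, maf)
  v
}

# Expand genotype counts (n0, n1, n2) per group into a 0/1/2 vector.
counts_to_dosage <- function(n0, n1, n2) {
  rep(c(0, 1, 2), c(n0, n1, n2))
}
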