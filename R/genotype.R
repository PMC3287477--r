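#' Genotype matrix container
#'
#' Bundles an additive-dosage matrix (samples x SNPs, entries 0/1/2 or `NA`)
#' with per-SNP metadata and sample identifiers. Columns are reordered on
#' construction so that, within each chromosome, SNPs are sorted by position;
#' all downstream LD-block construction relies on that order.
#'
#' @param dosages numeric matrix, samples in rows, SNPs in columns; entries
#'   must be 0, 1, 2 or `NA` (minor-allele counts).
#' @param snp_meta data frame with columns `snp_id`, `chrom`, `pos`
#'   (1-based bp), one row per SNP column.
#' @param sample_ids character vector of sample identifiers, one per row.
#' @return an object of class `genotype_matrix` with elements `dosages`
#'   (colnames set to SNP ids), `snp_meta` and `sample_ids`.
#' @export
genotype_matrix <- function(dosages, snp_meta, sample_ids = NULL) {
  dosages <- as.matrix(dosages)
  storage.mode(dosages) <- "double"
  if (is.null(sample_ids)) {
    sample_ids <- rownames(dosages)
    if (is.null(sample_ids)) sample_ids <- paste0("sample", seq_len(nrow(dosages)))
  }
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  need <- c("snp_id", "chrom", "pos")
  if (!all(need %in% names(snp_meta))) {
    stop("snp_meta must have columns: ", paste(need, collapse = ", "))
  }
  snp_meta$snp_id <- as.character(snp_meta$snp_id)
  snp_meta$chrom <- as.character(snp_meta$chrom)
  snp_meta$pos <- as.integer(snp_meta$pos)
  if (nrow(snp_meta) != ncol(dosages)) {
    stop("snp_meta has ", nrow(snp_meta), " rows but dosages has ",
         ncol(dosages), " columns")
  }
  if (length(sample_ids) != nrow(dosages)) {
    stop("sample_ids length does not match the number of dosage rows")
  }
  if (anyDuplicated(snp_meta$snp_id)) stop("duplicated snp_id in snp_meta")
  if (any(snp_meta$pos < 0, na.rm = TRUE)) stop("SNP positions must be non-negative")
  bad <- dosages[!is.na(dosages)]
  if (length(bad) && !all(bad %in% c(0, 1, 2))) {
    stop("dosage entries must be 0, 1, 2 or NA")
  }
  ord <- order(snp_meta$chrom, snp_meta$pos)
  snp_meta <- snp_meta[ord, , drop = FALSE]
  rownames(snp_meta) <- NULL
  dosages <- dosages[, ord, drop = FALSE]
  colnames(dosages) <- snp_meta$snp_id
  rownames(dosages) <- sample_ids
  structure(
    list(dosages = dosages, snp_meta = snp_meta,
         sample_ids = as.character(sample_ids)),
    class = "genotype_matrix"
  )
}

# Internal fast path: wrap components already known to satisfy the
# invariants (sorted, validated, consistent dims) without re-checking.
.genotype_matrix_unsafe <- function(dosages, snp_meta, sample_ids) {
  colnames(dosages) <- snp_meta$snp_id
  rownames(dosages) <- sample_ids
  structure(list(dosages = dosages, snp_meta = snp_meta,
                 sample_ids = sample_ids),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix: ", length(x$sample_ids), " samples x ",
      nrow(x$snp_meta), " SNPs on ",
      length(unique(x$snp_meta$chrom)), " chromosome(s)\n", sep = "")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosages)

#' Read a samples-by-SNPs dosage table
#'
#' Plain TSV dialect: first column holds sample ids, remaining columns are
#' named by SNP id and contain additive dosages 0/1/2 (`NA` for missing).
#' SNP coordinates come from a separate map (see [read_snp_map()]); SNPs
#' absent from the map are dropped with a warning.
#'
#' @param path TSV file path.
#' @param snp_map data frame with `snp_id`, `chrom`, `pos` columns.
#' @return a [genotype_matrix()].
#' @export
read_genotype_tsv <- function(path, snp_map) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) < 2) stop("genotype TSV needs a sample-id column plus SNP columns")
  sample_ids <- as.character(tab[[1]])
  dos <- as.matrix(tab[, -1, drop = FALSE])
  .genotype_from_columns(dos, sample_ids, snp_map, path)
}

#' Read a PLINK-style .raw dosage file
#'
#' Expects the `FID IID PAT MAT SEX PHENOTYPE` preamble followed by one
#' dosage column per SNP; trailing counted-allele suffixes (`rs123_A`) are
#' stripped from SNP names. `IID` is used as the sample id.
#'
#' @inheritParams read_genotype_tsv
#' @return a [genotype_matrix()].
#' @export
read_genotype_raw <- function(path, snp_map) {
  tab <- utils::read.table(path, header = TRUE, check.names = FALSE,
                           stringsAsFactors = FALSE)
  pre <- c("FID", "IID", "PAT", "MAT", "SEX", "PHENOTYPE")
  if (!all(pre %in% names(tab)[seq_len(6)])) {
    stop(".raw file must start with columns ", paste(pre, collapse = " "))
  }
  sample_ids <- as.character(tab$IID)
  dos <- as.matrix(tab[, -seq_len(6), drop = FALSE])
  colnames(dos) <- sub("_[ACGT]$", "", colnames(dos))
  .genotype_from_columns(dos, sample_ids, snp_map, path)
}

.genotype_from_columns <- function(dos, sample_ids, snp_map, path) {
  snp_map <- as.data.frame(snp_map, stringsAsFactors = FALSE)
  keep <- colnames(dos) %in% snp_map$snp_id
  if (!all(keep)) {
    warning(sum(!keep), " SNP column(s) in ", path,
            " missing from the SNP map; dropped")
    dos <- dos[, keep, drop = FALSE]
  }
  meta <- snp_map[match(colnames(dos), snp_map$snp_id), c("snp_id", "chrom", "pos")]
  genotype_matrix(dos, meta, sample_ids)
}

#' Read a SNP map
#'
#' Three-column TSV with header `chrom`, `snp_id`, `pos` (any order).
#'
#' @param path TSV file path.
#' @return data frame with columns `snp_id`, `chrom`, `pos`.
#' @export
read_snp_map <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("chrom", "snp_id", "pos")
  if (!all(need %in% names(tab))) {
    stop("SNP map must have columns: ", paste(need, collapse = ", "))
  }
  data.frame(snp_id = as.character(tab$snp_id), chrom = as.character(tab$chrom),
             pos = as.integer(tab$pos), stringsAsFactors = FALSE)
}

#' Read a PLINK .bim file as a SNP map
#'
#' Six whitespace-separated columns without header:
#' chromosome, SNP id, genetic distance, bp position, allele 1, allele 2.
#'
#' @param path .bim file path.
#' @return data frame with columns `snp_id`, `chrom`, `pos`.
#' @export
read_bim <- function(path) {
  tab <- utils::read.table(path, header = FALSE, stringsAsFactors = FALSE)
  if (ncol(tab) != 6) stop(".bim file must have exactly 6 columns")
  data.frame(snp_id = as.character(tab[[2]]), chrom = as.character(tab[[1]]),
             pos = as.integer(tab[[4]]), stringsAsFactors = FALSE)
}

#' Read a phenotype/covariate table
#'
#' TSV keyed by `sample_id` with a binary `status` column (1 = case,
#' 0 = control) and optional covariate columns. Rows are reordered to match
#' `sample_ids` when supplied; samples missing from the table are an error.
#'
#' @param path TSV file path.
#' @param sample_ids optional character vector fixing the sample order.
#' @return data frame with `sample_id`, `status` and any covariates.
#' @export
read_phenotype_tsv <- function(path, sample_ids = NULL) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!all(c("sample_id", "status") %in% names(tab))) {
    stop("phenotype table must have columns sample_id and status")
  }
  tab$sample_id <- as.character(tab$sample_id)
  if (!is.null(sample_ids)) {
    idx <- match(as.character(sample_ids), tab$sample_id)
    if (anyNA(idx)) {
      stop("phenotype table is missing samples: ",
           paste(utils::head(sample_ids[is.na(idx)], 5), collapse = ", "))
    }
    tab <- tab[idx, , drop = FALSE]
    rownames(tab) <- NULL
  }
  if (!all(tab$status %in% c(0, 1))) stop("status must be coded 0/1")
  tab
}

#' Write a genotype matrix to the plain TSV dialect
#'
#' @param g a [genotype_matrix()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_genotype_tsv <- function(g, path) {
  tab <- data.frame(sample_id = g$sample_ids, g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a genotype matrix in the PLINK-style .raw dialect
#'
#' @inheritParams write_genotype_tsv
#' @param phenotype optional phenotype table providing the PHENOTYPE column
#'   (PLINK convention: 1 = control, 2 = case; -9 when absent).
#' @return `path`, invisibly.
#' @export
write_genotype_raw <- function(g, path, phenotype = NULL) {
  phe <- if (is.null(phenotype)) rep(-9L, length(g$sample_ids)) else
    phenotype$status + 1L
  tab <- data.frame(FID = g$sample_ids, IID = g$sample_ids, PAT = 0L, MAT = 0L,
                    SEX = 0L, PHENOTYPE = phe, g$dosages,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(tab, path, sep = " ", quote = FALSE, row.names = FALSE)
  invisible(path)
}
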