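#' Read gene annotations from BED
#'
#' BED is 0-based half-open; coordinates are converted to 1-based inclusive
#' on read (`start + 1`, `end` unchanged). Only the first four columns
#' (chrom, start, end, name) are used.
#'
#' @param path BED file path.
#' @return data frame with columns `gene_id`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (ncol(tab) < 4) stop("gene BED needs at least 4 columns (chrom, start, end, name)")
  out <- data.frame(gene_id = as.character(tab[[4]]), chrom = as.character(tab[[1]]),
                    start = as.integer(tab[[2]]) + 1L, end = as.integer(tab[[3]]),
                    stringsAsFactors = FALSE)
  .validate_genes(out)
}

#' Read gene annotations from a 4-column TSV
#'
#' Header `gene_id`, `chrom`, `start`, `end`; coordinates already 1-based
#' inclusive (no conversion).
#'
#' @param path TSV file path.
#' @return data frame as in [read_bed_genes()].
#' @export
read_gene_tsv <- function(path) {
  tab <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  need <- c("gene_id", "chrom", "start", "end")
  if (!all(need %in% names(tab))) {
    stop("gene TSV must have columns: ", paste(need, collapse = ", "))
  }
  out <- data.frame(gene_id = as.character(tab$gene_id),
                    chrom = as.character(tab$chrom),
                    start = as.integer(tab$start), end = as.integer(tab$end),
                    stringsAsFactors = FALSE)
  .validate_genes(out)
}

.validate_genes <- function(genes) {
  if (any(genes$start > genes$end)) stop("gene with start > end")
  if (anyDuplicated(genes$gene_id)) stop("duplicated gene_id in annotation")
  genes
}

#' Map SNPs to their nearest gene within a window
#'
#' Each SNP is assigned to the closest gene on its chromosome: distance 0
#' when the SNP lies inside the gene body, otherwise the bp gap to the
#' nearer gene boundary. Only genes within `window_bp` are eligible
#' (default 500 kb, the usual regulatory-neighbourhood radius); equidistant
#' ties go to the lexicographically smaller `gene_id` for determinism.
#' SNPs on chromosomes absent from the annotation are reported unmapped
#' with a warning.
#'
#' @param snp_meta data frame with `snp_id`, `chrom`, `pos`.
#' @param genes gene annotation data frame (`gene_id`, `chrom`, `start`,
#'   `end`, 1-based inclusive).
#' @param window_bp maximum distance from a gene boundary, >= 0.
#' @return list with `map` (data frame `snp_id`, `gene_id`, `distance`) and
#'   `unmapped` (character vector of SNP ids).
#' @export
map_snps_to_genes <- function(snp_meta, genes, window_bp = 500000) {
  stopifnot(window_bp >= 0)
  genes <- .validate_genes(as.data.frame(genes, stringsAsFactors = FALSE))
  snp_meta <- as.data.frame(snp_meta, stringsAsFactors = FALSE)
  gene_hit <- rep(NA_character_, nrow(snp_meta))
  dist_hit <- rep(NA_real_, nrow(snp_meta))
  unknown_chrom <- FALSE
  for (chr in unique(snp_meta$chrom)) {
    si <- which(snp_meta$chrom == chr)
    gi <- which(genes$chrom == chr)
    if (!length(gi)) {
      unknown_chrom <- TRUE
      next
    }
    pos <- snp_meta$pos[si]
    # order candidate genes by id so that which.min keeps the smaller id on ties
    gsub_ <- genes[gi, , drop = FALSE]
    gsub_ <- gsub_[order(gsub_$gene_id), , drop = FALSE]
    dmat <- vapply(seq_len(nrow(gsub_)), function(k) {
      pmax(0, pmax(gsub_$start[k] - pos, pos - gsub_$end[k]))
    }, numeric(length(pos)))
    dmat <- matrix(dmat, nrow = length(pos))
    best <- apply(dmat, 1, which.min)
    bestd <- dmat[cbind(seq_along(best), best)]
    ok <- bestd <= window_bp
    gene_hit[si[ok]] <- gsub_$gene_id[best[ok]]
    dist_hit[si[ok]] <- bestd[ok]
  }
  if (unknown_chrom) {
    warning("some SNPs lie on chromosomes absent from the gene annotation; ",
            "reported unmapped")
  }
  mapped <- !is.na(gene_hit)
  list(
    map = data.frame(snp_id = snp_meta$snp_id[mapped],
                     gene_id = gene_hit[mapped],
                     distance = dist_hit[mapped], stringsAsFactors = FALSE),
    unmapped = snp_meta$snp_id[!mapped]
  )
}

#' Read a GMT gene-set collection
#'
#' Standard GMT: one set per line, tab-separated `set_id`, description,
#' then member genes. Duplicate genes within a line are removed with a
#' warning; lines with fewer than 3 fields are an error naming the line
#' number; an empty file yields an empty collection with a warning.
#'
#' @param path GMT file path.
#' @return named list of character vectors (set id -> member genes), with a
#'   `descriptions` attribute; class `gene_set_collection`.
#' @export
read_gmt <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    warning("empty GMT file: ", path)
    return(structure(setNames(list(), character(0)),
                     descriptions = character(0),
                     class = "gene_set_collection"))
  }
  sets <- list()
  descs <- character(0)
  for (i in seq_along(lines)) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3) {
      stop("malformed GMT line ", i, ": need set id, description and >= 1 gene")
    }
    genes <- fields[-(1:2)]
    genes <- genes[nzchar(genes)]
    if (anyDuplicated(genes)) {
      warning("duplicated gene(s) in set '", fields[1], "' (line ", i,
              "); deduplicated")
      genes <- unique(genes)
    }
    sets[[fields[1]]] <- genes
    descs[fields[1]] <- fields[2]
  }
  structure(sets, descriptions = descs, class = "gene_set_collection")
}

#' Write a gene-set collection to GMT
#'
#' @param sets named list of character vectors (or `gene_set_collection`).
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(sets, path) {
  descs <- attr(sets, "descriptions")
  lines <- vapply(names(sets), function(s) {
    d <- if (!is.null(descs) && !is.na(descs[s])) descs[s] else "na"
    paste(c(s, d, sets[[s]]), collapse = "\t")
  }, character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Write gene annotations as BED (1-based inclusive -> 0-based half-open)
#'
#' @param genes gene annotation data frame.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_bed_genes <- function(genes, path) {
  tab <- data.frame(genes$chrom, genes$start - 1L, genes$end, genes$gene_id)
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
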