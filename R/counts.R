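#' Construct a cells x genes count matrix
#'
#' The package-wide container for raw UMI/read counts. Orientation is fixed
#' as cells in rows and genes in columns everywhere; readers convert on
#' ingest. Entries must be non-negative integers.
#'
#' @param values Numeric matrix of non-negative integer counts
#'   (cells x genes).
#' @param cell_ids Character vector of unique cell identifiers, one per row.
#' @param gene_ids Character vector of unique gene identifiers, one per
#'   column.
#' @return A numeric matrix of class `count_matrix` with `cell_ids` as
#'   rownames and `gene_ids` as colnames.
#' @export
count_matrix <- function(values, cell_ids = rownames(values),
                         gene_ids = colnames(values)) {
  values <- as.matrix(values)
  if (is.null(cell_ids)) cell_ids <- paste0("cell", seq_len(nrow(values)))
  if (is.null(gene_ids)) gene_ids <- paste0("gene", seq_len(ncol(values)))
  cell_ids <- as.character(cell_ids)
  gene_ids <- as.character(gene_ids)
  if (length(cell_ids) != nrow(values))
    stop("cell_ids length (", length(cell_ids), ") != number of rows (",
         nrow(values), ")")
  if (length(gene_ids) != ncol(values))
    stop("gene_ids length (", length(gene_ids), ") != number of columns (",
         ncol(values), ")")
  if (anyDuplicated(cell_ids)) stop("cell_ids must be unique")
  if (anyDuplicated(gene_ids)) stop("gene_ids must be unique")
  storage.mode(values) <- "double"
  if (anyNA(values) || any(!is.finite(values)))
    stop("counts contain missing or non-finite entries")
  if (any(values < 0)) stop("counts contain negative entries")
  if (any(values != round(values))) stop("counts contain non-integer entries")
  dimnames(values) <- list(cell_ids, gene_ids)
  class(values) <- c("count_matrix", class(values))
  values
}

#' @export
print.count_matrix <- function(x, ...) {
  cat("count_matrix:", nrow(x), "cells x", ncol(x), "genes;",
      sprintf("%.1f%% zero entries\n", 100 * mean(x == 0)))
  invisible(x)
}

# strip class so arithmetic on the raw matrix behaves normally
unclass_matrix <- function(x) {
  x <- unclass(x)
  class(x) <- NULL
  as.matrix(x)
}

#' Read a count matrix from disk
#'
#' Supports the 10x Genomics MTX triplet layout (`matrix.mtx` +
#' `barcodes.tsv` + `features.tsv`/`genes.tsv`, genes x cells on disk,
#' transposed to cells x genes on load) and dense CSV/TSV with a header row
#' of gene ids and a first column of cell ids. Duplicate gene identifiers
#' in a features file are disambiguated by suffixing `.1`, `.2`, ...
#'
#' @param path For `mtx_10x`, the directory holding the triplet (or the
#'   matrix file itself); for `csv`/`tsv`, the file.
#' @param format One of `"mtx_10x"`, `"csv"`, `"tsv"`.
#' @return A [count_matrix].
#' @export
read_counts <- function(path, format = c("mtx_10x", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_10x") {
    dir <- if (dir.exists(path)) path else dirname(path)
    find_one <- function(names) {
      for (nm in names) {
        f <- file.path(dir, nm)
        if (file.exists(f)) return(f)
      }
      stop("missing file: none of [", paste(names, collapse = ", "),
           "] found in ", dir)
    }
    mtx_file <- find_one(c("matrix.mtx", "matrix.mtx.gz"))
    bc_file <- find_one(c("barcodes.tsv", "barcodes.tsv.gz"))
    ft_file <- find_one(c("features.tsv", "genes.tsv", "features.tsv.gz",
                          "genes.tsv.gz"))
    m <- Matrix::readMM(mtx_file)       # genes x cells on disk
    barcodes <- readLines(bc_file)
    feat <- utils::read.table(ft_file, sep = "\t", header = FALSE,
                              stringsAsFactors = FALSE)
    gene_ids <- as.character(feat[[1L]])
    if (length(barcodes) != ncol(m))
      stop("barcode file lists ", length(barcodes),
           " cells but matrix has ", ncol(m), " columns")
    if (length(gene_ids) != nrow(m))
      stop("features file lists ", length(gene_ids),
           " genes but matrix has ", nrow(m), " rows")
    gene_ids <- make.unique(gene_ids)
    vals <- t(as.matrix(m))
    return(count_matrix(vals, cell_ids = barcodes, gene_ids = gene_ids))
  }
  if (!file.exists(path)) stop("missing file: ", path)
  sep <- if (format == "csv") "," else "\t"
  df <- utils::read.table(path, sep = sep, header = TRUE, row.names = 1,
                          check.names = FALSE, stringsAsFactors = FALSE)
  count_matrix(as.matrix(df), cell_ids = rownames(df), gene_ids = colnames(df))
}

#' Write a count matrix to disk
#'
#' Inverse of [read_counts]: `mtx_10x` writes the triplet (genes x cells,
#' MatrixMarket coordinate integer); `csv`/`tsv` write a dense table with
#' gene-id header and cell-id first column. Round-trips are lossless for
#' integer counts.
#'
#' @param X A [count_matrix].
#' @param path Directory (`mtx_10x`) or file (`csv`/`tsv`).
#' @param format Output format.
#' @return `path`, invisibly.
#' @export
write_counts <- function(X, path, format = c("mtx_10x", "csv", "tsv")) {
  format <- match.arg(format)
  if (format == "mtx_10x") {
    if (!dir.exists(path)) dir.create(path, recursive = TRUE)
    m <- Matrix::Matrix(t(unclass_matrix(X)), sparse = TRUE)
    Matrix::writeMM(m, file.path(path, "matrix.mtx"))
    writeLines(rownames(X), file.path(path, "barcodes.tsv"))
    utils::write.table(
      data.frame(id = colnames(X), name = colnames(X),
                 type = "Gene Expression"),
      file.path(path, "features.tsv"), sep = "\t", quote = FALSE,
      row.names = FALSE, col.names = FALSE)
    return(invisible(path))
  }
  sep <- if (format == "csv") "," else "\t"
  df <- as.data.frame(unclass_matrix(X))
  utils::write.table(df, path, sep = sep, quote = FALSE,
                     col.names = NA, row.names = TRUE)
  invisible(path)
}

#' Quality-control filter configuration
#'
#' Defaults follow the standard droplet-QC protocol for plant root
#' datasets: drop cells with fewer than 200 detected genes, then drop genes
#' detected in fewer than 20 remaining cells. Mitochondrial and
#' detected-feature window filters are off unless set.
#'
#' @param min_genes_per_cell Cells with fewer detected (nonzero) genes are
#'   removed.
#' @param min_cells_per_gene Genes detected in fewer remaining cells are
#'   removed.
#' @param max_mito_fraction If set, cells whose summed counts over genes
#'   matching `mito_gene_prefix` exceed this fraction of their total counts
#'   are removed.
#' @param mito_gene_prefix Character vector of id prefixes marking
#'   mitochondrial genes (no universal list exists across plant genomes, so
#'   the prefix set is configurable).
#' @param min_features,max_features If set, cells outside this detected-gene
#'   window are removed.
#' @return A `filter_config` list.
#' @export
filter_config <- function(min_genes_per_cell = 200, min_cells_per_gene = 20,
                          max_mito_fraction = NULL,
                          mito_gene_prefix = c("ATMG", "MT-", "mt-"),
                          min_features = NULL, max_features = NULL) {
  stopifnot(min_genes_per_cell >= 0, min_cells_per_gene >= 0)
  if (!is.null(max_mito_fraction))
    stopifnot(max_mito_fraction >= 0, max_mito_fraction <= 1)
  if (!is.null(min_features) && !is.null(max_features) &&
      min_features > max_features)
    stop("min_features must be <= max_features")
  structure(list(min_genes_per_cell = min_genes_per_cell,
                 min_cells_per_gene = min_cells_per_gene,
                 max_mito_fraction = max_mito_fraction,
                 mito_gene_prefix = mito_gene_prefix,
                 min_features = min_features,
                 max_features = max_features),
            class = "filter_config")
}

#' Filter low-quality cells and genes
#'
#' Applies, in order: removal of genes with zero counts in all cells; cell
#' filters (detected-gene minimum, optional mitochondrial fraction cap,
#' optional detected-feature window); then removal of genes detected in too
#' few remaining cells. Filtering is idempotent: a second pass with the
#' same configuration removes nothing.
#'
#' @param X A [count_matrix].
#' @param cfg A [filter_config].
#' @return List with `counts` (the filtered [count_matrix]) and `report`
#'   (list of `removed_cells` and `removed_genes` id vectors).
#' @export
filter_cells_genes <- function(X, cfg = filter_config()) {
  stopifnot(inherits(X, "count_matrix"), inherits(cfg, "filter_config"))
  V <- unclass_matrix(X)
  removed_genes <- character(0)
  removed_cells <- character(0)

  zero_gene <- colSums(V) == 0
  removed_genes <- c(removed_genes, colnames(V)[zero_gene])
  V <- V[, !zero_gene, drop = FALSE]
  if (ncol(V) == 0)
    stop("all genes removed: every gene had zero counts in all cells")

  detected <- rowSums(V > 0)
  drop_cell <- detected < cfg$min_genes_per_cell
  if (!is.null(cfg$max_mito_fraction)) {
    is_mito <- Reduce(`|`, lapply(cfg$mito_gene_prefix,
                                  function(p) startsWith(colnames(V), p)))
    mito_frac <- if (any(is_mito))
      rowSums(V[, is_mito, drop = FALSE]) / pmax(rowSums(V), 1)
    else rep(0, nrow(V))
    drop_cell <- drop_cell | (mito_frac > cfg$max_mito_fraction)
  }
  if (!is.null(cfg$min_features)) drop_cell <- drop_cell | (detected < cfg$min_features)
  if (!is.null(cfg$max_features)) drop_cell <- drop_cell | (detected > cfg$max_features)
  removed_cells <- rownames(V)[drop_cell]
  V <- V[!drop_cell, , drop = FALSE]
  if (nrow(V) == 0)
    stop("all cells removed: cell filters (min_genes_per_cell/",
         "max_mito_fraction/feature window) emptied the matrix")

  det_cells <- colSums(V > 0)
  drop_gene <- det_cells < cfg$min_cells_per_gene | det_cells == 0
  removed_genes <- c(removed_genes, colnames(V)[drop_gene])
  V <- V[, !drop_gene, drop = FALSE]
  if (ncol(V) == 0)
    stop("all genes removed: min_cells_per_gene emptied the matrix")

  list(counts = count_matrix(V),
       report = list(removed_cells = removed_cells,
                     removed_genes = removed_genes))
}

#' Library-size normalization with optional log transform
#'
#' Scales each cell's counts to sum to `scale_total` (counts-per-ten-
#' thousand by default) and, if requested, applies `log1p`. Cells with zero
#' total counts pass through as all-zero rows. Rank order of genes within a
#' cell is preserved.
#'
#' @param X A [count_matrix].
#' @param scale_total Target per-cell total before the log transform.
#' @param log_transform Apply `log(1 + v)` elementwise after scaling.
#' @return Numeric matrix of class `normalized_matrix` (cells x genes) with
#'   attribute `scale_total`.
#' @export
normalize_counts <- function(X, scale_total = 1e4, log_transform = TRUE) {
  stopifnot(inherits(X, "count_matrix"))
  if (!is.numeric(scale_total) || length(scale_total) != 1 || scale_total <= 0)
    stop("scale_total must be a positive number")
  V <- unclass_matrix(X)
  totals <- rowSums(V)
  sf <- ifelse(totals > 0, scale_total / totals, 0)
  V <- V * sf
  if (log_transform) V <- log1p(V)
  structure(V, scale_total = scale_total, log_transform = log_transform,
            class = c("normalized_matrix", class(V)))
}

#' @export
print.normalized_matrix <- function(x, ...) {
  cat("normalized_matrix:", nrow(x), "cells x", ncol(x), "genes",
      "(scale_total =", attr(x, "scale_total"),
      if (isTRUE(attr(x, "log_transform"))) ", log1p)" else ")", "\n")
  invisible(x)
}

#' Zero-fraction and detected-gene summary
#'
#' Diagnostic for comparing the sparsity of datasets (plant droplet data
#' are typically denser than mammalian data) and for verifying corruption
#' bookkeeping.
#'
#' @param X A [count_matrix].
#' @return List with `sparsity` (fraction of zero entries),
#'   `detected_per_cell` (integer vector), and `detected_quantiles`.
#' @export
sparsity_summary <- function(X) {
  stopifnot(inherits(X, "count_matrix"))
  V <- unclass_matrix(X)
  det <- rowSums(V > 0)
  list(sparsity = mean(V == 0),
       detected_per_cell = det,
       detected_quantiles = stats::quantile(det, c(0, .25, .5, .75, 1)))
}
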