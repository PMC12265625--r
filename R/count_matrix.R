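#' Cell-by-gene UMI count container
#'
#' The universal expression container of the pipeline: a sparse cells x genes
#' matrix of non-negative integer UMI counts plus a per-cell metadata table.
#' Recognised metadata columns are `total_umis`, `unspliced_fraction`,
#' `doublet_score`, `sample`, `age_pcw` and `cluster`; all are optional.
#'
#' @param counts matrix or Matrix, cells in rows, genes in columns, with
#'   unique row (cell) and column (gene) names. Entries must be non-negative
#'   integers.
#' @param cell_meta optional data.frame of per-cell metadata, one row per
#'   cell in the same order as `rownames(counts)`. If it carries a
#'   `total_umis` column it must equal the row sums of `counts`.
#' @return an object of class `count_matrix`: a list with elements `counts`
#'   (a `dgCMatrix`) and `cell_meta` (a data.frame keyed by cell id).
#' @examples
#' m <- count_matrix(matrix(0:3, 2, 2,
#'   dimnames = list(c("c1", "c2"), c("g1", "g2"))))
#' dim(m)
#' @export
count_matrix <- function(counts, cell_meta = NULL) {
  dn <- dimnames(counts)
  counts <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                    "generalMatrix"), "CsparseMatrix")
  if (!is.null(dn)) dimnames(counts) <- dn  # Matrix drops empty dimnames
  if ((nrow(counts) > 0 && is.null(rownames(counts))) ||
      (ncol(counts) > 0 && is.null(colnames(counts)))) {
    stop("counts must carry cell (row) and gene (column) names")
  }
  if (anyDuplicated(rownames(counts))) stop("duplicate cell ids")
  if (anyDuplicated(colnames(counts))) stop("duplicate gene ids")
  x <- counts@x
  if (length(x)) {
    if (any(x < 0)) {
      bad <- which(as.matrix(counts) < 0, arr.ind = TRUE)[1, ]
      stop(sprintf("negative count at cell '%s', gene '%s'",
                   rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
    }
    if (any(x != round(x))) {
      bad <- which(as.matrix(counts) != round(as.matrix(counts)),
                   arr.ind = TRUE)[1, ]
      stop(sprintf("non-integer count at cell '%s', gene '%s'",
                   rownames(counts)[bad[1]], colnames(counts)[bad[2]]))
    }
  }
  if (is.null(cell_meta)) {
    cell_meta <- data.frame(row.names = rownames(counts))
  } else {
    cell_meta <- as.data.frame(cell_meta)
    if (nrow(cell_meta) != nrow(counts)) {
      stop("cell_meta must have one row per cell")
    }
    rownames(cell_meta) <- rownames(counts)
    if ("total_umis" %in% names(cell_meta)) {
      rs <- Matrix::rowSums(counts)
      off <- which(cell_meta$total_umis != rs)
      if (length(off)) {
        stop(sprintf("total_umis disagrees with row sum for cell '%s'",
                     rownames(counts)[off[1]]))
      }
    }
  }
  structure(list(counts = counts, cell_meta = cell_meta),
            class = "count_matrix")
}

#' @export
dim.count_matrix <- function(x) dim(x$counts)

#' @export
dimnames.count_matrix <- function(x) dimnames(x$counts)

#' Cell and gene ids of a count matrix
#' @param m a `count_matrix`.
#' @return character vector of ids.
#' @export
cell_ids <- function(m) rownames(m$counts)

#' @rdname cell_ids
#' @export
gene_ids <- function(m) colnames(m$counts)

#' Per-cell total UMI counts
#'
#' Row sums of the count matrix, recomputed from the counts (the stored
#' `total_umis` metadata is validated at construction, so the two agree).
#'
#' @param m a `count_matrix`.
#' @return named numeric vector of totals.
#' @export
cell_totals <- function(m) Matrix::rowSums(m$counts)

#' @export
print.count_matrix <- function(x, ...) {
  cat(sprintf("count_matrix: %d cells x %d genes (%.1f%% nonzero)\n",
              nrow(x$counts), ncol(x$counts),
              100 * length(x$counts@x) / prod(dim(x$counts))))
  if (ncol(x$cell_meta)) {
    cat("cell_meta:", paste(names(x$cell_meta), collapse = ", "), "\n")
  }
  invisible(x)
}

#' Subset a count matrix
#'
#' @param x a `count_matrix`.
#' @param i cell index (logical, integer or names).
#' @param j gene index.
#' @param ... ignored.
#' @return a `count_matrix` over the selected cells and genes.
#' @export
`[.count_matrix` <- function(x, i, j, ...) {
  if (missing(i)) i <- seq_len(nrow(x$counts))
  if (missing(j)) j <- seq_len(ncol(x$counts))
  count_matrix(x$counts[i, j, drop = FALSE],
               x$cell_meta[i, , drop = FALSE])
}
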