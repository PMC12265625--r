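#' Read and write count matrices on disk
#'
#' Counts are stored as a Matrix Market sparse file `matrix.mtx` (cells in
#' rows) with two TSV sidecars: `cells.tsv` (column `cell_id` plus any
#' metadata columns) and `genes.tsv` (column `gene_id`). The round trip is
#' lossless; on read, row sums are recomputed and checked against a
#' `total_umis` column when present.
#'
#' @param path directory holding (or to hold) `matrix.mtx`, `cells.tsv` and
#'   `genes.tsv`.
#' @return `read_counts` returns a [count_matrix()]; `write_counts` returns
#'   `path`, invisibly.
#' @export
read_counts <- function(path) {
  files <- file.path(path, c("matrix.mtx", "cells.tsv", "genes.tsv"))
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    stop("missing count matrix file(s): ", paste(missing, collapse = ", "))
  }
  counts <- Matrix::readMM(files[1])
  cells <- read.delim(files[2], stringsAsFactors = FALSE,
                      check.names = FALSE)
  genes <- read.delim(files[3], stringsAsFactors = FALSE,
                      check.names = FALSE)
  if (!"cell_id" %in% names(cells)) stop("cells.tsv lacks a cell_id column")
  if (!"gene_id" %in% names(genes)) stop("genes.tsv lacks a gene_id column")
  if (nrow(cells) != nrow(counts) || nrow(genes) != ncol(counts)) {
    stop(sprintf(
      "dimension mismatch: matrix is %d x %d but sidecars list %d cells, %d genes",
      nrow(counts), ncol(counts), nrow(cells), nrow(genes)))
  }
  dimnames(counts) <- list(cells$cell_id, genes$gene_id)
  meta <- cells[setdiff(names(cells), "cell_id")]
  count_matrix(counts, if (ncol(meta)) meta else NULL)
}

#' @param m a [count_matrix()].
#' @rdname read_counts
#' @export
write_counts <- function(m, path) {
  stopifnot(inherits(m, "count_matrix"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  Matrix::writeMM(m$counts, file.path(path, "matrix.mtx"))
  cells <- cbind(data.frame(cell_id = cell_ids(m)), m$cell_meta)
  write.table(cells, file.path(path, "cells.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(gene_id = gene_ids(m)),
              file.path(path, "genes.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read gene-to-locus annotation
#'
#' Accepts two dialects, auto-detected from the header line: a 3-column TSV
#' (`gene`, `chrom`, `position`) or a BED-style table (`chrom`, `start`,
#' `end`, `gene`; 0-based half-open, position taken as `start`). Chromosome
#' labels are normalized by stripping a leading "chr". Output rows are
#' sorted by (chromosome, position) with chromosomes in genome order
#' 1-22, X, Y.
#'
#' @param path TSV file path.
#' @return data.frame with columns `gene`, `chrom`, `position`, sorted.
#' @export
read_gene_annotation <- function(path) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  cols <- names(tab)
  if (all(c("gene", "chrom", "position") %in% cols)) {
    ann <- data.frame(gene = as.character(tab$gene),
                      chrom = normalize_chrom(tab$chrom),
                      position = as.integer(tab$position))
  } else if (all(c("chrom", "start", "end", "gene") %in% cols)) {
    ann <- data.frame(gene = as.character(tab$gene),
                      chrom = normalize_chrom(tab$chrom),
                      position = as.integer(tab$start))
  } else {
    stop("unrecognized annotation header: expected (gene, chrom, position) ",
         "or BED-style (chrom, start, end, gene); got: ",
         paste(cols, collapse = ", "))
  }
  if (anyDuplicated(ann$gene)) {
    stop("duplicate gene id in annotation: ",
         ann$gene[anyDuplicated(ann$gene)])
  }
  if (any(ann$position < 0)) stop("negative position in annotation")
  gene_annotation(ann)
}

#' Construct a gene annotation table
#'
#' @param ann data.frame with columns `gene`, `chrom`, `position`.
#' @return the same data.frame, chromosome-normalized and sorted by
#'   (chromosome, position); genes unique.
#' @export
gene_annotation <- function(ann) {
  stopifnot(all(c("gene", "chrom", "position") %in% names(ann)))
  if (anyDuplicated(ann$gene)) stop("duplicate gene id in annotation")
  ann$chrom <- normalize_chrom(ann$chrom)
  ann <- ann[order(chrom_rank(ann$chrom), ann$position, ann$gene), ,
             drop = FALSE]
  rownames(ann) <- NULL
  ann[c("gene", "chrom", "position")]
}

#' Read and write named gene sets
#'
#' Stored as a two-column TSV (`set`, `gene`). Within a set, genes must be
#' unique and the set non-empty.
#'
#' @param path TSV file path.
#' @return `read_gene_sets` returns a named list of character vectors.
#' @export
read_gene_sets <- function(path) {
  if (!file.exists(path)) stop("gene set file not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("set", "gene") %in% names(tab)))
  sets <- split(as.character(tab$gene), tab$set)
  sets <- sets[unique(as.character(tab$set))]  # keep file order
  for (nm in names(sets)) {
    if (anyDuplicated(sets[[nm]])) {
      stop("duplicate gene in set '", nm, "'")
    }
  }
  sets
}

#' @param sets named list of character vectors.
#' @rdname read_gene_sets
#' @export
write_gene_sets <- function(sets, path) {
  tab <- data.frame(set = rep(names(sets), lengths(sets)),
                    gene = unlist(sets, use.names = FALSE))
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a spatial transcript table
#'
#' One row per detected transcript: `gene`, `x`, `y` (micrometres), `cell`
#' (segmented cell id, or the empty string/"unassigned"/NA when the
#' transcript falls outside any cell) and `in_nucleus` (0/1 or
#' logical).
#'
#' @param path TSV file path.
#' @return data.frame of class `spatial_transcripts`.
#' @export
read_spatial_transcripts <- function(path) {
  if (!file.exists(path)) stop("transcript table not found: ", path)
  tab <- read.delim(path, stringsAsFactors = FALSE)
  spatial_transcripts(tab)
}

#' Construct a spatial transcript table
#' @param tab data.frame with columns `gene`, `x`, `y`, `cell`, `in_nucleus`.
#' @return validated data.frame of class `spatial_transcripts`.
#' @export
spatial_transcripts <- function(tab) {
  stopifnot(all(c("gene", "x", "y", "cell", "in_nucleus") %in% names(tab)))
  if (!all(is.finite(tab$x)) || !all(is.finite(tab$y))) {
    stop("non-finite transcript coordinates")
  }
  tab$in_nucleus <- as.logical(tab$in_nucleus)
  tab$cell <- as.character(tab$cell)
  tab$cell[is.na(tab$cell) | tab$cell %in% c("", "unassigned", "UNASSIGNED")] <- NA
  class(tab) <- c("spatial_transcripts", "data.frame")
  tab
}

# Report genes dropped at a cross-file join; exact, case-sensitive matching.
report_dropped_genes <- function(wanted, available, context) {
  dropped <- setdiff(wanted, available)
  if (length(dropped)) {
    message(sprintf("%s: dropped %d/%d genes absent from target (%s%s)",
                    context, length(dropped), length(wanted),
                    paste(head(dropped, 5), collapse = ", "),
                    if (length(dropped) > 5) ", ..." else ""))
  }
  dropped
}
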