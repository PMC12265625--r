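#' Quality-control thresholds
#'
#' Bundles every QC threshold the pipeline uses. Round 1 acts per cell
#' (UMIs, unspliced fraction, doublet score); round 2 acts per cluster on
#' the pooled build; the spatial thresholds apply to targeted in situ
#' panels, with different minima for fetal tissue and tumours.
#'
#' Boundary semantics follow the wording they implement: "fewer than" /
#' "less than" are strict (`<`), "at least" is `>=`. A cell with exactly
#' 1000 UMIs, unspliced fraction exactly 0.10 and doublet score 0.39
#' passes; a doublet score of exactly 0.40 fails (under the default
#' direction).
#'
#' @param min_umis round-1 minimum total UMIs (fail when below).
#' @param min_unspliced_fraction round-1 minimum unspliced molecule
#'   fraction (fail when below).
#' @param doublet_score_cutoff round-1 doublet-score cutoff.
#' @param round2_min_umis UMI level defining "low" cells in round 2.
#' @param round2_low_fraction cluster removed when at least this fraction
#'   of its cells is low.
#' @param spatial_min_genes,spatial_min_transcripts per-cell minima for
#'   spatial data, length-2 named vectors (`fetal`, `tumour`).
#' @param spatial_norm_total per-cell total after spatial normalization.
#' @return list of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_umis = 1000,
                          min_unspliced_fraction = 0.1,
                          doublet_score_cutoff = 0.4,
                          round2_min_umis = 1800,
                          round2_low_fraction = 0.40,
                          spatial_min_genes = c(fetal = 8, tumour = 3),
                          spatial_min_transcripts = c(fetal = 20, tumour = 5),
                          spatial_norm_total = 10000) {
  t <- list(min_umis = min_umis,
            min_unspliced_fraction = min_unspliced_fraction,
            doublet_score_cutoff = doublet_score_cutoff,
            round2_min_umis = round2_min_umis,
            round2_low_fraction = round2_low_fraction,
            spatial_min_genes = spatial_min_genes,
            spatial_min_transcripts = spatial_min_transcripts,
            spatial_norm_total = spatial_norm_total)
  stopifnot(all(unlist(t) >= 0),
            min_unspliced_fraction <= 1, round2_low_fraction <= 1)
  structure(t, class = "qc_thresholds")
}

#' Round-1 per-cell QC filter
#'
#' A cell fails iff its total UMIs fall below `min_umis`, its unspliced
#' fraction falls below `min_unspliced_fraction`, or its doublet score is
#' on the doublet side of `doublet_score_cutoff`. By default a high score
#' marks a doublet (`doublet_direction = "high"`: fail when score >= 0.4),
#' matching DoubletFinder semantics; `"low"` removes cells scoring below
#' the cutoff instead. Criteria whose metadata column is absent are
#' skipped with a warning.
#'
#' @param m a [count_matrix()]; `unspliced_fraction` and `doublet_score`
#'   are read from its cell metadata, totals from the counts.
#' @param thresholds a [qc_thresholds()].
#' @param doublet_direction `"high"` (default) or `"low"`.
#' @return list with `pass` (named logical) and `reasons` (list of
#'   character vectors drawn from `low_umis`, `low_unspliced`, `doublet`;
#'   empty iff the cell passes).
#' @export
filter_cells <- function(m, thresholds = qc_thresholds(),
                         doublet_direction = c("high", "low")) {
  stopifnot(inherits(m, "count_matrix"))
  doublet_direction <- match.arg(doublet_direction)
  n <- nrow(m$counts)
  reasons <- rep(list(character()), n)
  totals <- cell_totals(m)
  low <- totals < thresholds$min_umis
  reasons[low] <- lapply(reasons[low], c, "low_umis")
  if (!is.null(m$cell_meta$unspliced_fraction)) {
    lowu <- m$cell_meta$unspliced_fraction < thresholds$min_unspliced_fraction
    reasons[lowu] <- lapply(reasons[lowu], c, "low_unspliced")
  } else {
    warning("cell_meta lacks unspliced_fraction; criterion skipped")
  }
  if (!is.null(m$cell_meta$doublet_score)) {
    dbl <- if (doublet_direction == "high") {
      m$cell_meta$doublet_score >= thresholds$doublet_score_cutoff
    } else {
      m$cell_meta$doublet_score < thresholds$doublet_score_cutoff
    }
    reasons[dbl] <- lapply(reasons[dbl], c, "doublet")
  } else {
    warning("cell_meta lacks doublet_score; criterion skipped")
  }
  pass <- lengths(reasons) == 0L
  names(pass) <- names(reasons) <- cell_ids(m)
  list(pass = pass, reasons = reasons)
}

#' Round-2 per-cluster QC filter
#'
#' After clustering, a cluster is removed when at least
#' `round2_low_fraction` (default 40%) of its cells have fewer than
#' `round2_min_umis` (default 1800) total UMIs.
#'
#' @param m a [count_matrix()].
#' @param clusters per-cell cluster labels (length = number of cells).
#' @param thresholds a [qc_thresholds()].
#' @return character vector of removed cluster labels (possibly empty).
#' @export
filter_clusters <- function(m, clusters, thresholds = qc_thresholds()) {
  stopifnot(inherits(m, "count_matrix"), length(clusters) == nrow(m$counts))
  totals <- cell_totals(m)
  removed <- character()
  labels <- if (is.factor(clusters)) levels(clusters) else
    unique(as.character(clusters))
  for (cl in labels) {
    idx <- which(as.character(clusters) == cl)
    if (!length(idx)) {
      warning("empty cluster '", cl, "' skipped")
      next
    }
    frac_low <- mean(totals[idx] < thresholds$round2_min_umis)
    if (frac_low >= thresholds$round2_low_fraction) removed <- c(removed, cl)
  }
  removed
}

#' QC and normalization of spatial transcript tables
#'
#' Keeps only transcripts assigned to a segmented nucleus, tabulates them
#' into a cell x gene count matrix, removes cells below the per-type gene
#' and transcript minima, then normalizes each kept cell to a fixed total
#' (default 10,000) followed by log(1 + x). Both the raw counts and the
#' normalized layer are returned.
#'
#' @param s a [spatial_transcripts()] table.
#' @param thresholds a [qc_thresholds()].
#' @param sample_type `"fetal"` (minima 8 genes / 20 transcripts) or
#'   `"tumour"` (3 genes / 5 transcripts).
#' @param panel optional character vector of panel genes; transcripts with
#'   other labels are dropped.
#' @return a [count_matrix()] of the kept cells with an extra element
#'   `lognorm` (dense matrix of log-normalized expression); zero rows with
#'   a warning when no cell survives.
#' @export
spatial_qc_normalize <- function(s, thresholds = qc_thresholds(),
                                 sample_type = c("fetal", "tumour"),
                                 panel = NULL) {
  stopifnot(inherits(s, "spatial_transcripts"))
  sample_type <- match.arg(sample_type)
  min_genes <- thresholds$spatial_min_genes[[sample_type]]
  min_tx <- thresholds$spatial_min_transcripts[[sample_type]]

  keep <- s$in_nucleus & !is.na(s$cell)
  if (!is.null(panel)) keep <- keep & s$gene %in% panel
  s <- s[keep, , drop = FALSE]
  genes <- if (is.null(panel)) sort(unique(s$gene)) else panel
  if (!nrow(s) || !length(genes)) {
    warning("no nuclear transcripts survive QC; returning empty result")
    empty <- matrix(0L, 0, length(genes), dimnames = list(character(), genes))
    out <- count_matrix(empty)
    out$lognorm <- empty
    return(out)
  }
  counts <- as.matrix(table(factor(s$cell), factor(s$gene, levels = genes)))
  names(dimnames(counts)) <- NULL
  ok <- rowSums(counts > 0) >= min_genes & rowSums(counts) >= min_tx
  counts <- counts[ok, , drop = FALSE]
  if (!nrow(counts)) {
    warning("no cells pass spatial QC; returning empty result")
    out <- count_matrix(counts)
    out$lognorm <- counts
    return(out)
  }
  norm <- counts / rowSums(counts) * thresholds$spatial_norm_total
  out <- count_matrix(counts, data.frame(total_umis = rowSums(counts),
                                         sample = sample_type))
  out$lognorm <- log1p(norm)
  out
}
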