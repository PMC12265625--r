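#' Depth-normalize and log-transform a count matrix
#'
#' Scales every cell to a fixed total (default 10,000 counts) and applies
#' log(1 + x); the convention used throughout for expression-level scoring.
#'
#' @param m a [count_matrix()].
#' @param total per-cell total after scaling.
#' @return dense cells x genes matrix of log-normalized expression.
#' @export
log_normalize <- function(m, total = 10000) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- cell_totals(m)
  totals[totals == 0] <- 1
  as.matrix(log1p(m$counts / totals * total))
}

#' Cell-cycle score
#'
#' The fraction of a cell's UMIs that fall in a set of well-known
#' cell-cycle genes; a proxy for active proliferation. Scale-free by
#' construction: multiplying a cell's counts by a constant leaves the
#' score unchanged.
#'
#' @param m a [count_matrix()].
#' @param cycle_genes character vector of cell-cycle gene ids.
#' @return named per-cell score in `[0, 1]`; cells with zero total counts
#'   score 0, with a warning.
#' @export
cell_cycle_score <- function(m, cycle_genes) {
  stopifnot(inherits(m, "count_matrix"), length(cycle_genes) >= 1)
  present <- intersect(cycle_genes, gene_ids(m))
  totals <- cell_totals(m)
  in_set <- if (length(present)) {
    Matrix::rowSums(m$counts[, present, drop = FALSE])
  } else {
    rep(0, length(totals))
  }
  zero <- totals == 0
  if (any(zero)) {
    warning(sum(zero), " cell(s) with zero total counts scored 0")
    totals[zero] <- 1
  }
  setNames(as.numeric(in_set / totals), cell_ids(m))
}

#' Percentage of cycling cells per cluster
#'
#' @param scores per-cell cell-cycle scores.
#' @param clusters per-cell cluster labels.
#' @param cutoff a cell is cycling when its score is strictly greater than
#'   this (default 0.01).
#' @return named numeric vector of per-cluster percentages.
#' @export
cycling_fraction <- function(scores, clusters, cutoff = 0.01) {
  stopifnot(length(scores) == length(clusters))
  out <- tapply(scores > cutoff, as.character(clusters), mean) * 100
  setNames(as.numeric(out), names(out))
}

#' Cluster gene enrichment
#'
#' A measure of overexpression in a cluster relative to all other clusters
#' pooled, combining mean expression and the fraction of non-zero cells:
#' \deqn{E(g,c) = \frac{\mu_{in} + \epsilon}{\mu_{out} + \epsilon}
#'   \times \frac{f_{in} + \epsilon}{f_{out} + \epsilon}}
#' with \eqn{\mu} the mean raw count, \eqn{f} the fraction of cells with a
#' non-zero count, and \eqn{\epsilon = 0.01}. Per-cluster rankings break
#' ties lexicographically on the gene id.
#'
#' @param m a [count_matrix()].
#' @param clusters per-cell cluster labels; at least two distinct clusters.
#' @param eps pseudocount stabilising both ratios.
#' @return object of class `enrichment_table`: list with `enrichment`
#'   (clusters x genes matrix) and `ranking` (named list of gene vectors,
#'   most enriched first).
#' @export
cluster_enrichment <- function(m, clusters, eps = 0.01) {
  stopifnot(inherits(m, "count_matrix"), length(clusters) == nrow(m$counts))
  clusters <- as.character(clusters)
  labs <- sort(unique(clusters))
  if (length(labs) < 2) stop("need at least two clusters for a contrast")
  genes <- gene_ids(m)
  enr <- matrix(NA_real_, length(labs), length(genes),
                dimnames = list(labs, genes))
  counts <- m$counts
  for (cl in labs) {
    inn <- clusters == cl
    mu_in <- Matrix::colMeans(counts[inn, , drop = FALSE])
    mu_out <- Matrix::colMeans(counts[!inn, , drop = FALSE])
    f_in <- Matrix::colMeans(counts[inn, , drop = FALSE] > 0)
    f_out <- Matrix::colMeans(counts[!inn, , drop = FALSE] > 0)
    enr[cl, ] <- ((mu_in + eps) / (mu_out + eps)) *
      ((f_in + eps) / (f_out + eps))
  }
  ranking <- lapply(labs, function(cl) {
    genes[order(-enr[cl, ], genes)]
  })
  names(ranking) <- labs
  structure(list(enrichment = enr, ranking = ranking),
            class = "enrichment_table")
}

#' Top enriched genes per cluster
#'
#' @param e an [cluster_enrichment()] table.
#' @param n genes per cluster (default 50).
#' @return named list of character vectors, one gene set per cluster.
#' @export
top_enriched_genes <- function(e, n = 50) {
  stopifnot(inherits(e, "enrichment_table"), n >= 1)
  lapply(e$ranking, head, n)
}

#' Parameters for signature scoring
#'
#' @param n_bins number of equal-size expression bins genes are grouped
#'   into (default 25).
#' @param n_controls_per_gene control genes drawn per signature gene from
#'   the same bin (default 100).
#' @param seed RNG seed for the control draws.
#' @return list of class `signature_score_params`.
#' @export
signature_score_params <- function(n_bins = 25, n_controls_per_gene = 100,
                                   seed = 1) {
  stopifnot(n_bins >= 2, n_controls_per_gene >= 1)
  structure(list(n_bins = n_bins, n_controls_per_gene = n_controls_per_gene,
                 seed = seed),
            class = "signature_score_params")
}

#' Gene-signature score with expression-matched controls
#'
#' Generalized gene-profile scoring: on log-normalized expression, each
#' gene is centred by its mean across cells ("relative expression"); genes
#' are ranked by aggregate expression and cut into `n_bins` equal-size
#' bins; for every signature gene, `n_controls_per_gene` control genes are
#' drawn (with replacement, excluding the gene itself) from its bin. The
#' score of a cell is the mean relative expression over the signature
#' minus the mean over the pooled control draws, so a bin-matched random
#' set scores zero in expectation.
#'
#' @param m a [count_matrix()].
#' @param set character vector of signature genes; genes absent from the
#'   matrix are dropped with a report.
#' @param params a [signature_score_params()].
#' @param controls optional explicit control gene vector overriding the
#'   bin-matched draw (used for calibration checks).
#' @return named per-cell numeric score.
#' @export
signature_score <- function(m, set, params = signature_score_params(),
                            controls = NULL) {
  stopifnot(inherits(m, "count_matrix"))
  genes <- gene_ids(m)
  if (length(set) > length(genes)) {
    stop("signature larger than the gene vocabulary")
  }
  report_dropped_genes(set, genes, "signature_score")
  set <- intersect(set, genes)
  if (!length(set)) stop("no signature gene present in the matrix")
  expr <- log_normalize(m)
  rel <- sweep(expr, 2, colMeans(expr))
  if (is.null(controls)) {
    agg <- colMeans(expr)
    bin <- ceiling(rank(agg, ties.method = "first") /
                     (length(genes) / params$n_bins))
    controls <- with_seed(params$seed, {
      unlist(lapply(set, function(g) {
        pool <- genes[bin == bin[match(g, genes)]]
        pool <- setdiff(pool, g)
        if (!length(pool)) g else
          sample(pool, params$n_controls_per_gene, replace = TRUE)
      }), use.names = FALSE)
    })
  }
  score <- rowMeans(rel[, set, drop = FALSE]) -
    rowMeans(rel[, controls, drop = FALSE])
  setNames(as.numeric(score), cell_ids(m))
}

#' De-overlap cancer driver gene sets
#'
#' Removes from every list any gene appearing in two or more input lists,
#' so that generic cancer drivers cannot dominate a single cancer's set.
#'
#' @param lists named list of character vectors (per-cancer gene lists).
#' @return named list of exclusive gene sets (possibly empty).
#' @export
build_driver_sets <- function(lists) {
  stopifnot(is.list(lists), !is.null(names(lists)))
  lists <- lapply(lists, unique)
  tally <- table(unlist(lists, use.names = FALSE))
  shared <- names(tally)[tally >= 2]
  lapply(lists, setdiff, shared)
}

#' Criteria for layer-maturation assignment
#'
#' @param top_n enriched genes per layer entering the signature.
#' @param early_expressed_cell_fraction genes detected (count >= 1) in more
#'   than this fraction of early-group cells are dropped, so the remaining
#'   genes reflect maturation (default 0.15).
#' @param min_gene_count within a cell, a gene counts as expressed iff its
#'   raw count is strictly greater than this (default 2).
#' @param min_set_fraction minimum fraction of a layer's filtered genes a
#'   cell must express to receive that layer's label (default 0.05).
#' @param other_label label for unassigned cells.
#' @return list of class `maturation_criteria`.
#' @export
maturation_criteria <- function(top_n = 50,
                                early_expressed_cell_fraction = 0.15,
                                min_gene_count = 2,
                                min_set_fraction = 0.05,
                                other_label = "Other") {
  stopifnot(top_n >= 1,
            early_expressed_cell_fraction > 0,
            early_expressed_cell_fraction < 1,
            min_set_fraction > 0, min_set_fraction < 1)
  structure(list(top_n = top_n,
                 early_expressed_cell_fraction = early_expressed_cell_fraction,
                 min_gene_count = min_gene_count,
                 min_set_fraction = min_set_fraction,
                 other_label = other_label),
            class = "maturation_criteria")
}

#' Assign fetal fibroblasts to maturing meningeal layers
#'
#' Scores each cell against per-layer signature gene sets (typically the
#' top 50 enriched genes per adult meningeal layer) after removing genes
#' already expressed early in development: a set gene detected (count >= 1)
#' in more than `early_expressed_cell_fraction` of early-group cells is
#' dropped. Within a cell a set gene is expressed iff its raw count
#' exceeds `min_gene_count`; the cell takes the label of the layer with
#' the highest expressed-gene fraction, provided that fraction reaches
#' `min_set_fraction`, and `other_label` otherwise. Ties go to the earlier
#' layer in `names(layer_sets)` (list layers in priority order, e.g. pia,
#' arachnoid, dura); ties are logged.
#'
#' @param m a [count_matrix()] whose metadata carries the timepoint.
#' @param layer_sets named list of per-layer gene vectors, in tie-break
#'   priority order.
#' @param criteria a [maturation_criteria()].
#' @param timepoints per-cell timepoint values; defaults to the `age_pcw`
#'   metadata column.
#' @param early_group timepoint values forming the "early" group for the
#'   expression filter; defaults to the two earliest distinct values
#'   (post-conceptional weeks 5-6 in the study design).
#' @return list with `labels` (named per-cell layer label),
#'   `filtered_sets` (the gene sets after the early filter),
#'   `timepoint_fractions` (timepoint x label matrix, rows summing to 1)
#'   and `timepoint_median_expression` (timepoint x layer matrix of the
#'   median over cells of the mean raw count across the filtered set).
#' @export
maturation_assign <- function(m, layer_sets,
                              criteria = maturation_criteria(),
                              timepoints = m$cell_meta$age_pcw,
                              early_group = NULL) {
  stopifnot(inherits(m, "count_matrix"), length(layer_sets) >= 1,
            !is.null(names(layer_sets)))
  if (is.null(timepoints)) stop("no timepoints: supply age_pcw metadata")
  stopifnot(length(timepoints) == nrow(m$counts))
  if (is.null(early_group)) {
    early_group <- head(sort(unique(timepoints)), 2)
  }
  early <- timepoints %in% early_group
  if (!any(early)) stop("no cells in the early timepoint group")

  counts <- m$counts
  filtered <- lapply(names(layer_sets), function(l) {
    gl <- intersect(layer_sets[[l]], gene_ids(m))
    report_dropped_genes(layer_sets[[l]], gene_ids(m),
                         paste0("maturation_assign[", l, "]"))
    det <- Matrix::colMeans(counts[early, gl, drop = FALSE] > 0)
    keep <- gl[det <= criteria$early_expressed_cell_fraction]
    if (!length(keep)) {
      warning("layer '", l, "' has no genes left after the early filter; ",
              "it will never be assigned")
    }
    keep
  })
  names(filtered) <- names(layer_sets)

  frac <- vapply(names(filtered), function(l) {
    gl <- filtered[[l]]
    if (!length(gl)) return(rep(0, nrow(counts)))
    Matrix::rowMeans(counts[, gl, drop = FALSE] > criteria$min_gene_count)
  }, numeric(nrow(counts)))
  frac <- matrix(frac, nrow = nrow(counts),
                 dimnames = list(cell_ids(m), names(filtered)))

  best <- apply(frac, 1, which.max)  # first max = priority order tie-break
  n_tied <- sum(apply(frac, 1, function(x) sum(x == max(x)) > 1 & max(x) > 0))
  if (n_tied > 0) {
    message("maturation_assign: ", n_tied,
            " cell(s) tied; resolved by layer priority order")
  }
  labels <- colnames(frac)[best]
  top_frac <- frac[cbind(seq_len(nrow(frac)), best)]
  labels[top_frac < criteria$min_set_fraction] <- criteria$other_label
  names(labels) <- cell_ids(m)

  tps <- sort(unique(timepoints))
  lab_levels <- c(names(filtered), criteria$other_label)
  tf <- t(vapply(tps, function(tp) {
    tab <- table(factor(labels[timepoints == tp], levels = lab_levels))
    as.numeric(tab / sum(tab))
  }, numeric(length(lab_levels))))
  dimnames(tf) <- list(as.character(tps), lab_levels)

  med <- t(vapply(tps, function(tp) {
    vapply(names(filtered), function(l) {
      gl <- filtered[[l]]
      if (!length(gl)) return(NA_real_)
      median(Matrix::rowMeans(counts[timepoints == tp, gl, drop = FALSE]))
    }, numeric(1))
  }, numeric(length(filtered))))
  dimnames(med) <- list(as.character(tps), names(filtered))

  list(labels = labels, filtered_sets = filtered,
       timepoint_fractions = tf, timepoint_median_expression = med)
}
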