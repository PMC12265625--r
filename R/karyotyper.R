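#' Parameters of the expression-based karyotyper
#'
#' @param expr_quantile quantile of within-cluster expression defining the
#'   gene-selection reference level (default 0.99).
#' @param expr_fraction_of_quantile a gene passes in a cluster when its
#'   value exceeds this fraction of that cluster's quantile (default 0.10).
#' @param min_cluster_fraction a gene is kept when it passes in at least
#'   this fraction of clusters (default 0.5, "at least half").
#' @param autosomes_only restrict to chromosomes 1-22 (default TRUE).
#' @param smoothing_window rolling-mean window along each chromosome, in
#'   genes (default 25); centered, truncated at chromosome boundaries.
#' @param n_pcs principal components for metacell clustering (default 5).
#' @param knn neighbours of the kNN graph (default 30).
#' @param max_copies largest copy-number state of the HMM (default 6).
#' @param emission_sd Gaussian emission standard deviation, in ploidy
#'   units (default 0.3): wide enough that single-window noise cannot flip
#'   a call, narrow enough that a 25-gene event can.
#' @param stay_probability HMM self-transition probability (default
#'   0.999).
#' @param leiden_resolution resolution of the Leiden partition.
#' @param min_metacell_size metacells smaller than this have their cells
#'   reassigned to the nearest larger metacell (centroid distance in PC
#'   space); isolated noisy cells would otherwise escape the averaging
#'   that copy-number calling relies on (default 5).
#' @param pooled_quantile compute the selection quantile over the pooled
#'   atlas instead of within each cluster (default FALSE).
#' @return list of class `karyotyper_params`.
#' @export
karyotyper_params <- function(expr_quantile = 0.99,
                              expr_fraction_of_quantile = 0.10,
                              min_cluster_fraction = 0.5,
                              autosomes_only = TRUE,
                              smoothing_window = 25,
                              n_pcs = 5,
                              knn = 30,
                              max_copies = 6,
                              emission_sd = 0.3,
                              stay_probability = 0.999,
                              leiden_resolution = 1.0,
                              min_metacell_size = 5,
                              pooled_quantile = FALSE) {
  stopifnot(smoothing_window >= 1, max_copies >= 2,
            expr_fraction_of_quantile > 0, expr_fraction_of_quantile < 1,
            min_cluster_fraction > 0, min_cluster_fraction < 1,
            emission_sd > 0, stay_probability > 0, stay_probability < 1)
  structure(list(expr_quantile = expr_quantile,
                 expr_fraction_of_quantile = expr_fraction_of_quantile,
                 min_cluster_fraction = min_cluster_fraction,
                 autosomes_only = autosomes_only,
                 smoothing_window = smoothing_window,
                 n_pcs = n_pcs, knn = knn, max_copies = max_copies,
                 emission_sd = emission_sd,
                 stay_probability = stay_probability,
                 leiden_resolution = leiden_resolution,
                 min_metacell_size = min_metacell_size,
                 pooled_quantile = pooled_quantile),
            class = "karyotyper_params")
}

#' Select informative genes from the reference atlas
#'
#' Keeps autosomal genes expressed at more than
#' `expr_fraction_of_quantile` times the `expr_quantile` expression level
#' in at least `min_cluster_fraction` of the atlas clusters; the quantile
#' is computed within each cluster (over the pooled atlas when
#' `pooled_quantile`). Output is ordered along the genome.
#'
#' @param atlas clusters x genes matrix of mean normalized expression.
#' @param annotation a [gene_annotation()] table covering the atlas genes.
#' @param params a [karyotyper_params()].
#' @return character vector of kept gene ids in (chromosome, position)
#'   order, with the matching annotation rows as attribute `annotation`.
#' @export
select_genes <- function(atlas, annotation, params = karyotyper_params()) {
  genes <- colnames(atlas)
  ann <- annotation[match(genes, annotation$gene), ]
  if (anyNA(ann$gene)) stop("atlas genes missing from annotation")
  if (params$pooled_quantile) {
    thr <- rep(params$expr_fraction_of_quantile *
                 quantile(atlas, params$expr_quantile, names = FALSE),
               nrow(atlas))
  } else {
    thr <- apply(atlas, 1, quantile, params$expr_quantile, names = FALSE) *
      params$expr_fraction_of_quantile
  }
  pass <- sweep(atlas, 1, thr, `>`)  # per-cluster thresholds, rowwise
  need <- ceiling(params$min_cluster_fraction * nrow(atlas))
  keep <- colSums(pass) >= need
  if (params$autosomes_only) keep <- keep & ann$chrom %in% AUTOSOMES
  kept <- genes[keep]
  if (length(kept) < 50) {
    stop("only ", length(kept),
         " genes survive selection; track too sparse to smooth")
  }
  ann_kept <- ann[keep, , drop = FALSE]
  ord <- order(chrom_rank(ann_kept$chrom), ann_kept$position, ann_kept$gene)
  kept <- kept[ord]
  attr(kept, "annotation") <- {
    a <- ann_kept[ord, , drop = FALSE]
    rownames(a) <- NULL
    a
  }
  kept
}

#' Depth-normalize cells to the median total
#'
#' Scales each cell's counts by (median total UMIs across cells) / (its
#' own total), so every normalized cell sums to the median depth.
#'
#' @param m a [count_matrix()].
#' @return dense cells x genes matrix of normalized expression.
#' @export
normalize_cells <- function(m) {
  stopifnot(inherits(m, "count_matrix"))
  totals <- cell_totals(m)
  if (any(totals == 0)) stop("cells with zero total counts cannot be normalized")
  as.matrix(m$counts * (median(totals) / totals))
}

#' Match each cell to its best-correlated reference cluster
#'
#' Pearson correlation over the kept genes between each cell's normalized
#' expression and every atlas cluster profile; the argmax wins, ties
#' broken lexicographically on the cluster label.
#'
#' @param norm cells x genes normalized expression (or a single cell's
#'   named vector).
#' @param atlas clusters x genes reference atlas.
#' @param kept_genes character vector from [select_genes()].
#' @return named character vector of matched cluster labels.
#' @export
match_reference <- function(norm, atlas, kept_genes) {
  if (is.null(dim(norm))) norm <- matrix(norm, 1, dimnames = list("cell", names(norm)))
  x <- t(norm[, kept_genes, drop = FALSE])
  y <- t(atlas[, kept_genes, drop = FALSE])
  sds <- apply(x, 2, stats::sd)
  if (any(sds == 0)) {
    stop("constant expression vector for cell(s) ",
         paste(head(colnames(x)[sds == 0], 3), collapse = ", "),
         ": correlation undefined")
  }
  cc <- cor(x, y)
  ord <- order(colnames(cc))  # lexicographic tie-break via first max
  cc <- cc[, ord, drop = FALSE]
  labels <- colnames(cc)[apply(cc, 1, which.max)]
  setNames(labels, rownames(norm))
}

# Centered rolling mean over the columns of each row, window truncated at
# the ends; NA entries are excluded from the window average.
runmean_rows <- function(X, w) {
  n <- ncol(X)
  h <- (w - 1L) %/% 2L
  lo <- pmax(seq_len(n) - h, 1L)
  hi <- pmin(seq_len(n) + h, n)
  isna <- is.na(X)
  X0 <- X
  X0[isna] <- 0
  cs <- cbind(0, t(apply(X0, 1, cumsum)))
  cn <- cbind(0, t(apply(!isna, 1, cumsum)))
  sums <- cs[, hi + 1L, drop = FALSE] - cs[, lo, drop = FALSE]
  cnts <- cn[, hi + 1L, drop = FALSE] - cn[, lo, drop = FALSE]
  out <- sums / cnts
  out[cnts == 0] <- NA
  dimnames(out) <- dimnames(X)
  out
}

#' Per-cell ploidy tracks along the genome
#'
#' For each cell: divide its normalized expression by the matched
#' reference profile and multiply by two (so a diploid gene sits at 2);
#' smooth with a centered rolling mean within each chromosome (windows
#' truncated at chromosome boundaries); then rescale the track so its
#' genome-wide median is exactly 2. Genes whose reference value is below
#' `1e-9` are masked from that cell's track before smoothing.
#'
#' @param norm cells x genes normalized expression.
#' @param atlas clusters x genes reference atlas.
#' @param matches per-cell matched cluster labels from
#'   [match_reference()].
#' @param kept_genes output of [select_genes()] (carries the ordered
#'   annotation).
#' @param params a [karyotyper_params()].
#' @return object of class `ploidy_track_set`: list with `tracks` (cells x
#'   kept genes matrix), `annotation` (kept-gene annotation) and
#'   `boundaries` (named list of chromosome index ranges).
#' @export
ploidy_tracks <- function(norm, atlas, matches, kept_genes,
                          params = karyotyper_params()) {
  ann <- attr(kept_genes, "annotation")
  if (is.null(ann)) stop("kept_genes must come from select_genes()")
  cells <- rownames(norm)
  ref <- atlas[matches, kept_genes, drop = FALSE]
  ratio <- 2 * norm[, kept_genes, drop = FALSE] / ref
  ratio[ref < 1e-9] <- NA

  smoothed <- matrix(NA_real_, nrow(ratio), ncol(ratio),
                     dimnames = dimnames(ratio))
  chroms <- unique(ann$chrom)
  boundaries <- list()
  for (ch in chroms) {
    idx <- which(ann$chrom == ch)
    boundaries[[ch]] <- range(idx)
    smoothed[, idx] <- runmean_rows(ratio[, idx, drop = FALSE],
                                    min(params$smoothing_window,
                                        length(idx)))
  }
  med <- apply(smoothed, 1, median, na.rm = TRUE)
  smoothed <- smoothed / med * 2
  structure(list(tracks = smoothed, annotation = ann,
                 boundaries = boundaries),
            class = "ploidy_track_set")
}

#' Group cells into metacells by ploidy profile
#'
#' PCA (centering on, scaling off) of the cell x gene ploidy matrix to
#' `n_pcs` components, a mutual k-nearest-neighbour graph (`k = min(knn,
#' n - 1)`; an edge is kept when each endpoint lists the other), and a
#' seeded Leiden partition.
#'
#' @param pt a `ploidy_track_set` from [ploidy_tracks()].
#' @param params a [karyotyper_params()].
#' @param seed RNG seed for the Leiden refinement.
#' @return named integer vector of metacell labels (1-based).
#' @export
metacells <- function(pt, params = karyotyper_params(), seed = 1) {
  X <- pt$tracks
  if (anyNA(X)) {
    X[is.na(X)] <- 2  # masked genes are treated as neutral ploidy
  }
  n <- nrow(X)
  if (n < 2) return(setNames(rep(1L, n), rownames(X)))
  if (sum(apply(X, 2, stats::var)) < 1e-12) {
    return(setNames(rep(1L, n), rownames(X)))  # identical tracks
  }
  npc <- min(params$n_pcs, n - 1L, ncol(X))
  pcs <- prcomp(X, center = TRUE, scale. = FALSE, rank. = npc)$x
  k <- min(params$knn, n - 1L)
  d <- as.matrix(dist(pcs))
  nn <- t(apply(d, 1, function(row) order(row)[2:(k + 1L)]))
  adj <- matrix(FALSE, n, n)
  adj[cbind(rep(seq_len(n), k), as.vector(nn))] <- TRUE
  adj <- adj & t(adj)  # mutual kNN
  g <- igraph::graph_from_adjacency_matrix(adj, mode = "undirected")
  part <- with_seed(seed, {
    igraph::cluster_leiden(g, objective_function = "modularity",
                           resolution = params$leiden_resolution,
                           n_iterations = 5)
  })
  mem <- as.integer(igraph::membership(part))
  # fold undersized metacells into the nearest adequately sized one, so
  # isolated noisy cells still benefit from track averaging
  sizes <- table(mem)
  small <- as.integer(names(sizes)[sizes < params$min_metacell_size])
  large <- as.integer(names(sizes)[sizes >= params$min_metacell_size])
  if (length(small) && length(large)) {
    centroids <- matrix(vapply(large, function(i) {
      colMeans(pcs[mem == i, , drop = FALSE])
    }, numeric(ncol(pcs))), nrow = ncol(pcs))
    for (cell in which(mem %in% small)) {
      d2 <- colSums((centroids - pcs[cell, ])^2)
      mem[cell] <- large[which.min(d2)]
    }
  }
  mem <- as.integer(factor(mem))  # relabel 1..n_metacells
  setNames(mem, rownames(X))
}

#' Viterbi path of the copy-number HMM
#'
#' Hidden states are integer copy numbers `0..max_copies` with Gaussian
#' emissions centred on the state value (standard deviation
#' `emission_sd`), a uniform initial distribution, and transitions that
#' stay with probability `stay_probability` (the remainder spread
#' uniformly over the other states). `NA` observations contribute no
#' emission evidence. Ties prefer the lower copy number.
#'
#' @param obs numeric vector of smoothed ploidy values.
#' @param max_copies largest state.
#' @param emission_sd Gaussian emission sd.
#' @param stay_probability diagonal transition probability.
#' @return integer vector of the most probable state path.
#' @export
hmm_viterbi <- function(obs, max_copies = 6, emission_sd = 0.3,
                        stay_probability = 0.999) {
  states <- 0:max_copies
  S <- length(states)
  n <- length(obs)
  if (n == 0) return(integer())
  log_stay <- log(stay_probability)
  log_move <- log((1 - stay_probability) / (S - 1))
  emit <- function(x) {
    if (is.na(x)) rep(0, S) else dnorm(x, states, emission_sd, log = TRUE)
  }
  delta <- matrix(-Inf, n, S)
  psi <- matrix(0L, n, S)
  delta[1, ] <- log(1 / S) + emit(obs[1])
  for (t in seq_len(n)[-1]) {
    for (s in seq_len(S)) {
      cand <- delta[t - 1, ] + ifelse(seq_len(S) == s, log_stay, log_move)
      psi[t, s] <- which.max(cand)
      delta[t, s] <- cand[psi[t, s]]
    }
    delta[t, ] <- delta[t, ] + emit(obs[t])
  }
  path <- integer(n)
  path[n] <- which.max(delta[n, ])
  if (n > 1) {
    for (t in rev(seq_len(n - 1))) path[t] <- psi[t + 1, path[t + 1]]
  }
  states[path]
}

#' Segment metacell ploidy tracks into integer copy numbers
#'
#' Runs the Viterbi HMM independently per chromosome on a (mean) ploidy
#' track and merges the state path into segments.
#'
#' @param track numeric vector over the kept genes (genome order).
#' @param annotation kept-gene annotation (from the track set).
#' @param params a [karyotyper_params()].
#' @return data.frame with columns `chrom`, `start`, `end` (gene indices
#'   into the track, inclusive), `n_genes`, `copy`; segments tile each
#'   chromosome without gaps or overlaps.
#' @export
call_copy_numbers <- function(track, annotation,
                              params = karyotyper_params()) {
  segs <- list()
  for (ch in unique(annotation$chrom)) {
    idx <- which(annotation$chrom == ch)
    path <- hmm_viterbi(track[idx], params$max_copies,
                        params$emission_sd, params$stay_probability)
    r <- rle(path)
    ends <- cumsum(r$lengths)
    starts <- ends - r$lengths + 1L
    segs[[ch]] <- data.frame(chrom = ch,
                             start = idx[starts], end = idx[ends],
                             n_genes = r$lengths, copy = r$values)
  }
  out <- do.call(rbind, segs)
  rownames(out) <- NULL
  out
}

#' Expression-based karyotyping of a cell population
#'
#' The full inference: select informative autosomal genes from the
#' reference atlas, depth-normalize the cells, match each cell to its
#' best-correlated reference cluster, compute smoothed per-cell ploidy
#' tracks, group cells into metacells by Leiden clustering of the tracks'
#' principal components, and segment each metacell's mean track into
#' integer copy numbers with a hidden Markov model.
#'
#' @param m a [count_matrix()] of the sample cells.
#' @param atlas clusters x genes reference atlas of mean normalized
#'   expression (the "normal" reference).
#' @param annotation a [gene_annotation()] covering the atlas genes.
#' @param params a [karyotyper_params()].
#' @param seed RNG seed (metacell clustering).
#' @return object of class `karyotype`: list with `kept_genes`,
#'   `annotation`, `matches`, `metacell` (per-cell labels), `tracks`
#'   (the `ploidy_track_set`), `metacell_tracks` (metacell x gene mean
#'   tracks), `calls` (named list of segment data.frames) and `params`.
#' @examples
#' ref <- generate_reference_atlas(4, 600, seed = 1)
#' sim <- simulate_cells(ref$atlas, ref$annotation, 60, depth = 5000,
#'                       seed = 2)
#' kt <- karyotype(sim$matrix, ref$atlas, ref$annotation, seed = 3)
#' summary(kt)
#' @export
karyotype <- function(m, atlas, annotation, params = karyotyper_params(),
                      seed = 1) {
  stopifnot(inherits(m, "count_matrix"))
  kept <- select_genes(atlas, annotation, params)
  norm <- normalize_cells(m)
  matches <- match_reference(norm, atlas, kept)
  pt <- ploidy_tracks(norm, atlas, matches, kept, params)
  mc <- metacells(pt, params, seed = seed)
  ids <- sort(unique(mc))
  mt <- t(vapply(ids, function(i) {
    colMeans(pt$tracks[mc == i, , drop = FALSE], na.rm = TRUE)
  }, numeric(ncol(pt$tracks))))
  rownames(mt) <- paste0("MC", ids)
  calls <- lapply(seq_along(ids), function(i) {
    call_copy_numbers(mt[i, ], pt$annotation, params)
  })
  names(calls) <- rownames(mt)
  structure(list(kept_genes = kept, annotation = pt$annotation,
                 matches = matches,
                 metacell = setNames(paste0("MC", mc), names(mc)),
                 tracks = pt, metacell_tracks = mt, calls = calls,
                 params = params, n_cells = nrow(m$counts)),
            class = "karyotype")
}

#' Chromosome-level copy calls of a karyotype
#'
#' Collapses each metacell's segments to one integer call per chromosome:
#' the copy number covering the most genes on that chromosome.
#'
#' @param kt a [karyotype()] object.
#' @return metacell x chromosome integer matrix.
#' @export
chromosome_copy_matrix <- function(kt) {
  stopifnot(inherits(kt, "karyotype"))
  chroms <- unique(kt$annotation$chrom)
  out <- matrix(NA_integer_, length(kt$calls), length(chroms),
                dimnames = list(names(kt$calls), chroms))
  for (mc in names(kt$calls)) {
    segs <- kt$calls[[mc]]
    for (ch in chroms) {
      s <- segs[segs$chrom == ch, ]
      w <- tapply(s$n_genes, s$copy, sum)
      out[mc, ch] <- as.integer(names(w)[which.max(w)])
    }
  }
  out
}

#' @export
print.karyotype <- function(x, ...) {
  cm <- chromosome_copy_matrix(x)
  aber <- rowSums(cm != 2)
  cat(sprintf("karyotype: %d cells in %d metacells over %d genes (%d chromosomes)\n",
              x$n_cells, length(x$calls), length(x$kept_genes), ncol(cm)))
  for (mc in rownames(cm)) {
    ev <- cm[mc, cm[mc, ] != 2, drop = TRUE]
    cat(sprintf("  %s (%d cells): %s\n", mc, sum(x$metacell == mc),
                if (aber[mc] == 0) "diploid" else
                  paste(sprintf("chr%s=%d", names(ev), ev), collapse = ", ")))
  }
  invisible(x)
}

#' @export
summary.karyotype <- function(object, ...) {
  structure(list(copy_matrix = chromosome_copy_matrix(object),
                 metacell_sizes = table(object$metacell)),
            class = "summary.karyotype")
}

#' @export
print.summary.karyotype <- function(x, ...) {
  cat("chromosome copy-number calls (metacell x chromosome):\n")
  print(x$copy_matrix)
  cat("metacell sizes:\n")
  print(x$metacell_sizes)
  invisible(x)
}

#' Plot metacell ploidy tracks
#'
#' One line per metacell along the genome-ordered kept genes, with
#' chromosome boundaries marked; diploid level (2) dashed.
#'
#' @param x a [karyotype()] object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.karyotype <- function(x, ...) {
  mt <- x$metacell_tracks
  graphics::matplot(t(mt), type = "l", lty = 1, xlab = "gene (genome order)",
                    ylab = "ploidy", ...)
  graphics::abline(h = 2, lty = 2, col = "grey40")
  b <- vapply(x$tracks$boundaries, `[`, numeric(1), 2)
  graphics::abline(v = b + 0.5, col = "grey80")
  graphics::axis(3, at = vapply(x$tracks$boundaries, mean, numeric(1)),
                 labels = names(x$tracks$boundaries), tick = FALSE,
                 cex.axis = 0.6)
  invisible(x)
}
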