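# Approximate number of annotated genes per human chromosome, used to
# apportion simulated genes across the genome. Only the proportions matter.
CHROM_GENE_COUNTS <- c(
  "1" = 2058, "2" = 1309, "3" = 1078, "4" = 752, "5" = 876, "6" = 1048,
  "7" = 989, "8" = 677, "9" = 786, "10" = 733, "11" = 1298, "12" = 1034,
  "13" = 327, "14" = 830, "15" = 613, "16" = 873, "17" = 1197, "18" = 270,
  "19" = 1472, "20" = 544, "21" = 234, "22" = 488, "X" = 842, "Y" = 71
)

#' Specify a clone carrying chromosome-scale copy-number events
#'
#' Ground-truth description of a simulated clone: the fraction of cells it
#' accounts for and the integer copy number of each affected chromosome
#' (diploid chromosomes are omitted).
#'
#' @param clone_id label for the clone.
#' @param fraction proportion of simulated cells in `[0, 1]` belonging to
#'   the clone; fractions over all clones must sum to at most 1 (the
#'   remainder is diploid).
#' @param events named integer vector, names chromosome labels
#'   ("1".."22", "X", "Y"), values copy numbers in 0..6.
#' @return an object of class `cna_spec`.
#' @examples
#' cna_spec("cloneA", 0.3, c("22" = 1, "9" = 3))
#' @export
cna_spec <- function(clone_id, fraction, events) {
  stopifnot(is.character(clone_id), length(clone_id) == 1L,
            is.numeric(fraction), length(fraction) == 1L,
            fraction >= 0, fraction <= 1)
  ev <- unlist(events)
  if (is.null(names(ev)) || any(!nzchar(names(ev)))) {
    stop("events must be a named vector: chromosome -> copy number")
  }
  names(ev) <- normalize_chrom(names(ev))
  if (!all(names(ev) %in% CHROMOSOMES)) {
    stop("unknown chromosome in events: ",
         paste(setdiff(names(ev), CHROMOSOMES), collapse = ", "))
  }
  if (any(ev != round(ev)) || any(ev < 0) || any(ev > 6)) {
    stop("copy numbers must be integers in 0..6")
  }
  structure(list(clone_id = clone_id, fraction = fraction,
                 events = setNames(as.integer(ev), names(ev))),
            class = "cna_spec")
}

#' Generate a reference atlas of cluster expression profiles
#'
#' Draws cluster mean-expression profiles from a log-normal prior and lays
#' the genes out along the genome: genes are apportioned to chromosomes in
#' proportion to real per-chromosome gene counts (largest-remainder
#' rounding) with strictly increasing positions within each chromosome.
#' This plays the role of a normal tissue atlas against which tumour cells
#' are karyotyped.
#'
#' @param n_clusters number of reference clusters (>= 2).
#' @param n_genes number of genes (>= 100).
#' @param seed integer RNG seed; identical seeds give identical output.
#' @param chromosomes chromosome labels to use (default the full genome,
#'   autosomes 1-22 plus X and Y).
#' @param meanlog,sdlog parameters of the log-normal profile prior.
#' @return list with `atlas` (n_clusters x n_genes matrix of mean
#'   normalized expression) and `annotation` (a [gene_annotation()] table).
#' @export
generate_reference_atlas <- function(n_clusters, n_genes, seed,
                                     chromosomes = CHROMOSOMES,
                                     meanlog = 0, sdlog = 1) {
  if (n_clusters < 2) stop("n_clusters must be >= 2")
  if (n_genes < 100) stop("n_genes must be >= 100")
  stopifnot(all(chromosomes %in% CHROMOSOMES))
  with_seed(seed, {
    # largest-remainder apportionment so chromosome counts sum to n_genes
    w <- CHROM_GENE_COUNTS[chromosomes] / sum(CHROM_GENE_COUNTS[chromosomes])
    raw <- w * n_genes
    alloc <- floor(raw)
    rem <- n_genes - sum(alloc)
    if (rem > 0) {
      top <- order(raw - alloc, decreasing = TRUE)[seq_len(rem)]
      alloc[top] <- alloc[top] + 1
    }
    genes <- sprintf("G%05d", seq_len(n_genes))
    chrom <- rep(chromosomes, alloc)
    position <- unlist(lapply(alloc, function(k) {
      cumsum(sample(1000:100000, k, replace = TRUE))
    }), use.names = FALSE)
    ann <- gene_annotation(data.frame(gene = genes, chrom = chrom,
                                      position = position))
    atlas <- matrix(rlnorm(n_clusters * n_genes, meanlog, sdlog),
                    nrow = n_clusters,
                    dimnames = list(sprintf("C%d", seq_len(n_clusters)),
                                    genes))
    list(atlas = atlas, annotation = ann)
  })
}

#' Simulate cells from an atlas, optionally carrying copy-number events
#'
#' Each cell is assigned a reference cluster (uniformly) and a clone
#' (deterministic rounded fractions, remainder diploid). Its expected
#' expression is the cluster profile with genes on an affected chromosome
#' scaled by `copy / 2`, renormalized to the requested sequencing depth;
#' counts are Poisson draws around that expectation (negative binomial when
#' `dispersion` is given).
#'
#' @param atlas,annotation output of [generate_reference_atlas()] (or
#'   compatible).
#' @param n_cells number of cells.
#' @param cna list of [cna_spec()] objects; fractions must sum to <= 1.
#' @param depth mean UMIs per cell (default 10000, the study's scale).
#' @param seed integer RNG seed.
#' @param dispersion optional negative-binomial size parameter; `NULL`
#'   (default) gives pure Poisson noise.
#' @return list with `matrix` (a [count_matrix()]) and `truth` (data.frame
#'   with columns `cell`, `clone`, `cluster`).
#' @export
simulate_cells <- function(atlas, annotation, n_cells, cna = list(),
                           depth = 10000, seed = 1, dispersion = NULL) {
  stopifnot(n_cells >= 1, depth > 0)
  genes <- colnames(atlas)
  ann <- annotation[match(genes, annotation$gene), ]
  if (anyNA(ann$gene)) stop("atlas genes missing from annotation")
  if (length(cna)) {
    stopifnot(all(vapply(cna, inherits, logical(1), "cna_spec")))
    for (cs in cna) {
      bad <- setdiff(names(cs$events), unique(ann$chrom))
      if (length(bad)) {
        stop("CNA event on chromosome absent from annotation: ",
             paste(bad, collapse = ", "))
      }
    }
    fr <- vapply(cna, `[[`, numeric(1), "fraction")
    if (sum(fr) > 1 + 1e-9) stop("clone fractions sum to more than 1")
  }
  with_seed(seed, {
    clone_names <- c(vapply(cna, `[[`, character(1), "clone_id"), "diploid")
    n_per <- c(round(vapply(cna, `[[`, numeric(1), "fraction") * n_cells))
    n_per <- c(n_per, n_cells - sum(n_per))
    if (n_per[length(n_per)] < 0) stop("clone fractions exceed cell count")
    clone <- sample(rep(clone_names, n_per))
    cluster <- sample(rownames(atlas), n_cells, replace = TRUE)

    # per-clone gene scaling: copy/2 on affected chromosomes, 1 elsewhere
    scale_for <- function(cl) {
      s <- rep(1, length(genes))
      if (cl != "diploid") {
        ev <- cna[[match(cl, clone_names)]]$events
        for (ch in names(ev)) s[ann$chrom == ch] <- ev[[ch]] / 2
      }
      s
    }
    counts <- matrix(0L, nrow = n_cells, ncol = length(genes),
                     dimnames = list(sprintf("cell_%04d", seq_len(n_cells)),
                                     genes))
    for (cl in unique(clone)) {
      s <- scale_for(cl)
      for (cu in unique(cluster[clone == cl])) {
        idx <- which(clone == cl & cluster == cu)
        mu <- atlas[cu, ] * s
        lambda <- depth * mu / sum(mu)
        draw <- if (is.null(dispersion)) {
          rpois(length(idx) * length(genes), lambda)
        } else {
          rnbinom(length(idx) * length(genes), size = dispersion,
                  mu = lambda)
        }
        counts[idx, ] <- matrix(draw, nrow = length(genes),
                                ncol = length(idx), byrow = FALSE) |> t()
      }
    }
    m <- count_matrix(counts,
                      data.frame(total_umis = rowSums(counts),
                                 sample = "sim"))
    truth <- data.frame(cell = rownames(counts), clone = clone,
                        cluster = cluster)
    list(matrix = m, truth = truth)
  })
}

#' Simulate a topic-structured count corpus
#'
#' Standard latent Dirichlet allocation generative draws: topic-gene
#' distributions from a symmetric Dirichlet(`beta`) prior, per-document
#' topic mixtures from Dirichlet(`alpha`), and `doc_len` tokens per
#' document. The true distributions are returned for round-trip tests.
#'
#' @param n_topics number of topics (>= 1).
#' @param vocab vocabulary size.
#' @param n_docs number of documents (cells).
#' @param doc_len tokens per document.
#' @param alpha document-topic Dirichlet concentration.
#' @param seed integer RNG seed.
#' @param beta topic-gene Dirichlet concentration (default 0.1, sparse
#'   distinct topics).
#' @return list with `matrix` (a [count_matrix()], documents as cells) and
#'   `truth` (list with `phi` = topics x genes, `theta` = docs x topics).
#' @export
simulate_topic_corpus <- function(n_topics, vocab, n_docs, doc_len, alpha,
                                  seed, beta = 0.1) {
  stopifnot(n_topics >= 1, vocab >= 2, n_docs >= 1, doc_len >= 1, alpha > 0)
  with_seed(seed, {
    rdirichlet <- function(n, conc, k) {
      g <- matrix(rgamma(n * k, shape = conc), nrow = n)
      g / rowSums(g)
    }
    genes <- sprintf("G%04d", seq_len(vocab))
    docs <- sprintf("doc_%04d", seq_len(n_docs))
    phi <- rdirichlet(n_topics, beta, vocab)
    dimnames(phi) <- list(sprintf("T%d", seq_len(n_topics)), genes)
    theta <- rdirichlet(n_docs, alpha, n_topics)
    dimnames(theta) <- list(docs, rownames(phi))
    counts <- matrix(0L, n_docs, vocab, dimnames = list(docs, genes))
    for (d in seq_len(n_docs)) {
      z <- rmultinom(1, doc_len, theta[d, ])[, 1]
      for (k in which(z > 0)) {
        counts[d, ] <- counts[d, ] + rmultinom(1, z[k], phi[k, ])[, 1]
      }
    }
    list(matrix = count_matrix(counts,
                               data.frame(total_umis = rowSums(counts))),
         truth = list(phi = phi, theta = theta))
  })
}

#' Simulate a layer-maturation gradient
#'
#' Emulates fetal fibroblasts maturing into distinct meningeal layers: each
#' layer has a signature gene set whose expression probability rises
#' monotonically with timepoint, both in cells of that layer (strongly) and
#' as a weak graded background in other layers. The two earliest timepoints
#' (post-conceptional weeks 5-6) express signature genes in well under 15%
#' of cells, so the signatures survive the maturation filter.
#'
#' @param layers layer labels, in tie-break priority order (default pia,
#'   arachnoid, dura).
#' @param n_timepoints number of timepoints (>= 2); mapped to PCW
#'   5, 6, 8, 10, ...
#' @param cells_per_point cells per (timepoint x layer) group; 0 gives an
#'   empty matrix.
#' @param genes_per_layer signature genes per layer.
#' @param seed integer RNG seed.
#' @param n_background extra unstructured genes (Poisson(0.5) everywhere).
#' @return list with `matrix` (a [count_matrix()] carrying `age_pcw` and
#'   `timepoint` metadata), `truth` (data.frame `cell`, `layer`,
#'   `timepoint`) and `layer_sets` (named list of signature gene vectors).
#' @export
simulate_layer_gradient <- function(layers = c("pia", "arachnoid", "dura"),
                                    n_timepoints = 4, cells_per_point = 150,
                                    genes_per_layer = 50, seed = 1,
                                    n_background = 200) {
  stopifnot(n_timepoints >= 2, length(layers) >= 1, genes_per_layer >= 1)
  pcw <- c(5, 6, seq(8, by = 2, length.out = max(0, n_timepoints - 2)))
  sig_genes <- lapply(seq_along(layers), function(i) {
    sprintf("%s_g%03d", toupper(layers[i]), seq_len(genes_per_layer))
  })
  names(sig_genes) <- layers
  bg_genes <- sprintf("BG_g%03d", seq_len(n_background))
  genes <- c(unlist(sig_genes, use.names = FALSE), bg_genes)

  grad <- seq(0, 1, length.out = n_timepoints)
  own_p <- 0.04 + 0.86 * grad^2      # P(signature gene on) in own layer
  leak_p <- 0.01 + 0.18 * grad       # graded background in other layers

  n_cells <- n_timepoints * length(layers) * cells_per_point
  if (n_cells == 0) {
    counts <- matrix(0L, 0, length(genes),
                     dimnames = list(character(), genes))
    return(list(
      matrix = count_matrix(counts, data.frame(age_pcw = numeric(),
                                               timepoint = integer())),
      truth = data.frame(cell = character(), layer = character(),
                         timepoint = integer()),
      layer_sets = sig_genes))
  }
  with_seed(seed, {
    tp <- rep(seq_len(n_timepoints), each = length(layers) * cells_per_point)
    layer <- rep(rep(layers, each = cells_per_point), n_timepoints)
    counts <- matrix(0L, n_cells, length(genes),
                     dimnames = list(sprintf("cell_%05d", seq_len(n_cells)),
                                     genes))
    for (i in seq_len(n_cells)) {
      for (l in layers) {
        gl <- sig_genes[[l]]
        if (l == layer[i]) {
          on <- runif(genes_per_layer) < own_p[tp[i]]
          counts[i, gl][on] <- 3L + rpois(sum(on), 3)
        } else {
          on <- runif(genes_per_layer) < leak_p[tp[i]]
          counts[i, gl][on] <- 1L + rpois(sum(on), 1)
        }
      }
    }
    counts[, bg_genes] <- rpois(n_cells * n_background, 0.5)
    meta <- data.frame(age_pcw = pcw[tp], timepoint = tp,
                       total_umis = rowSums(counts))
    list(matrix = count_matrix(counts, meta),
         truth = data.frame(cell = rownames(counts), layer = layer,
                            timepoint = tp),
         layer_sets = sig_genes)
  })
}

#' Generate a QC boundary fixture
#'
#' Emits the full 3 x 3 x 3 grid of cells straddling each single-cell QC
#' boundary: total UMIs 999/1000/1001, unspliced fraction 0.09/0.10/0.11
#' and doublet score 0.39/0.40/0.41, with ground-truth pass/fail flags
#' under the documented rule (fail iff UMIs < 1000, or unspliced fraction
#' < 0.1, or doublet score >= 0.4).
#'
#' @param seed integer RNG seed (governs how each cell's total is spread
#'   over genes).
#' @return list with `matrix` (a [count_matrix()]) and `truth` (data.frame
#'   `cell`, `pass`).
#' @export
generate_qc_fixture <- function(seed = 1) {
  grid <- expand.grid(total = c(999L, 1000L, 1001L),
                      unspliced = c(0.09, 0.10, 0.11),
                      doublet = c(0.39, 0.40, 0.41))
  with_seed(seed, {
    n_genes <- 30
    counts <- t(vapply(grid$total, function(tot) {
      rmultinom(1, tot, rep(1, n_genes))[, 1]
    }, integer(n_genes)))
    dimnames(counts) <- list(sprintf("qc_%02d", seq_len(nrow(grid))),
                             sprintf("G%03d", seq_len(n_genes)))
    meta <- data.frame(total_umis = grid$total,
                       unspliced_fraction = grid$unspliced,
                       doublet_score = grid$doublet,
                       sample = "qcfix")
    pass <- grid$total >= 1000 & grid$unspliced >= 0.1 & grid$doublet < 0.4
    list(matrix = count_matrix(counts, meta),
         truth = data.frame(cell = rownames(counts), pass = pass))
  })
}
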