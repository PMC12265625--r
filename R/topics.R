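# Expand a docs x genes count matrix into 0-based (doc, word) token
# streams for the Gibbs samplers.
tokenize_counts <- function(counts) {
  tm <- methods::as(methods::as(Matrix::Matrix(counts, sparse = TRUE),
                                "generalMatrix"), "TsparseMatrix")
  n <- rep(seq_along(tm@x), tm@x)
  list(doc = tm@i[n], word = tm@j[n])
}

#' Fit an LDA topic model on a count matrix
#'
#' Collapsed Gibbs sampling over token-topic assignments; documents are
#' cells (or samples) and words are gene UMIs. The returned matrices are
#' posterior point estimates from the final sampler state. A fixed seed
#' gives an identical model.
#'
#' @param m a [count_matrix()]; every document (cell) must contain at
#'   least one count.
#' @param K number of topics (the study-scale default is 35; K = 1 is a
#'   degenerate special case returning the corpus distribution).
#' @param alpha document-topic concentration (default `50 / K`).
#' @param eta topic-gene concentration (default 0.1).
#' @param iterations Gibbs sweeps (default 1000).
#' @param seed RNG seed.
#' @return object of class `topic_model`: `K`, `phi` (K x genes, rows sum
#'   to 1), `theta` (docs x K, rows sum to 1), `vocabulary`,
#'   hyperparameters and the per-sweep token log-likelihood trace.
#' @export
fit_lda <- function(m, K = 35, alpha = 50 / K, eta = 0.1,
                    iterations = 1000, seed = 1) {
  stopifnot(inherits(m, "count_matrix"), K >= 1, iterations >= 1)
  totals <- cell_totals(m)
  if (any(totals == 0)) {
    stop("empty document(s): ",
         paste(head(cell_ids(m)[totals == 0], 3), collapse = ", "))
  }
  vocab <- gene_ids(m)
  docs <- cell_ids(m)
  if (K == 1) {
    phi <- matrix(Matrix::colSums(m$counts) / sum(m$counts), 1,
                  dimnames = list("T1", vocab))
    theta <- matrix(1, length(docs), 1, dimnames = list(docs, "T1"))
    return(structure(list(K = 1L, phi = phi, theta = theta,
                          vocabulary = vocab, alpha = alpha, eta = eta,
                          iterations = iterations, seed = seed,
                          loglik = numeric()),
                     class = "topic_model"))
  }
  tok <- tokenize_counts(m$counts)
  fit <- with_seed(seed, {
    lda_gibbs_cpp(tok$doc, tok$word, length(docs), length(vocab),
                  as.integer(K), alpha, eta, as.integer(iterations))
  })
  dimnames(fit$phi) <- list(sprintf("T%d", seq_len(K)), vocab)
  dimnames(fit$theta) <- list(docs, rownames(fit$phi))
  structure(list(K = as.integer(K), phi = fit$phi, theta = fit$theta,
                 vocabulary = vocab, alpha = alpha, eta = eta,
                 iterations = iterations, seed = seed,
                 loglik = as.numeric(fit$loglik)),
            class = "topic_model")
}

#' @export
print.topic_model <- function(x, ...) {
  cat(sprintf("topic_model: K = %d topics over %d genes, %d documents\n",
              x$K, length(x$vocabulary), nrow(x$theta)))
  cat(sprintf("  alpha = %.3g, eta = %.3g, %d Gibbs sweeps, seed %d\n",
              x$alpha, x$eta, x$iterations, x$seed))
  invisible(x)
}

#' Specificity-filtered topic-gene ranking
#'
#' For each topic, the specificity of a gene is its topic probability
#' normalized by that gene's probability summed across all topics; genes
#' at or above `specificity_threshold` are retained and then sorted by
#' their unnormalized topic probability (descending; ties broken
#' lexicographically on the gene id).
#'
#' @param model a [fit_lda()] model.
#' @param specificity_threshold retain genes with specificity at or above
#'   this value (0 keeps every gene and reduces to a probability sort).
#' @return object of class `topic_gene_ranking`: a named list (one
#'   data.frame per topic with columns `gene`, `specificity`,
#'   `probability`) with the threshold as attribute.
#' @export
rank_topic_genes <- function(model, specificity_threshold) {
  stopifnot(inherits(model, "topic_model"),
            specificity_threshold >= 0, specificity_threshold <= 1)
  phi <- model$phi
  spec <- sweep(phi, 2, colSums(phi), `/`)
  out <- lapply(rownames(phi), function(t) {
    keep <- which(spec[t, ] >= specificity_threshold)
    ord <- keep[order(-phi[t, keep], colnames(phi)[keep])]
    data.frame(gene = colnames(phi)[ord],
               specificity = as.numeric(spec[t, ord]),
               probability = as.numeric(phi[t, ord]))
  })
  names(out) <- rownames(phi)
  structure(out, class = "topic_gene_ranking",
            specificity_threshold = specificity_threshold)
}

#' Transfer fitted topics to new cells
#'
#' Restricts the topic-gene matrix to the genes shared with the target
#' (renormalizing each topic over the shared genes, with a report of
#' dropped genes) and infers per-cell topic weights by fold-in Gibbs
#' sampling with the topics frozen.
#'
#' @param model a [fit_lda()] model.
#' @param target a [count_matrix()] (e.g. a spatial panel); gene matching
#'   is exact and case-sensitive.
#' @param sweeps fold-in Gibbs sweeps (default 100).
#' @param seed RNG seed.
#' @return target cells x topics matrix of weights, rows summing to 1.
#'   Cells with no shared-gene counts get uniform weights, with a warning.
#' @export
transfer_topics_cells <- function(model, target, sweeps = 100, seed = 1) {
  stopifnot(inherits(model, "topic_model"), inherits(target, "count_matrix"))
  shared <- intersect(model$vocabulary, gene_ids(target))
  report_dropped_genes(model$vocabulary, gene_ids(target),
                       "transfer_topics_cells")
  if (!length(shared)) stop("no shared genes between model and target")
  phi <- model$phi[, shared, drop = FALSE]
  phi <- phi / rowSums(phi)
  counts <- target$counts[, shared, drop = FALSE]
  docs <- cell_ids(target)
  theta <- matrix(1 / model$K, length(docs), model$K,
                  dimnames = list(docs, rownames(model$phi)))
  nonempty <- Matrix::rowSums(counts) > 0
  if (any(!nonempty)) {
    warning(sum(!nonempty),
            " cell(s) without shared-gene counts given uniform weights")
  }
  if (any(nonempty)) {
    sub <- counts[nonempty, , drop = FALSE]
    tok <- tokenize_counts(sub)
    th <- with_seed(seed, {
      lda_fold_in_cpp(tok$doc, tok$word, sum(nonempty), phi, model$alpha,
                      as.integer(sweeps))
    })
    theta[nonempty, ] <- th
  }
  theta
}

#' Predict method for topic models
#'
#' `predict(model, newdata)` is fold-in topic transfer; see
#' [transfer_topics_cells()].
#'
#' @param object a `topic_model`.
#' @param newdata a [count_matrix()].
#' @param ... passed to [transfer_topics_cells()].
#' @return cells x topics weight matrix.
#' @export
predict.topic_model <- function(object, newdata, ...) {
  transfer_topics_cells(object, newdata, ...)
}

#' Transfer fitted topics to bulk expression profiles
#'
#' Each bulk profile is treated as a single document over the genes it
#' shares with the model, rescaled to a fixed token budget, and folded in
#' like any other document. Per-group contributions are the mean over
#' member samples, renormalized so every group sums to exactly 1.
#'
#' @param model a [fit_lda()] model.
#' @param bulk samples x genes matrix of non-negative expression values
#'   (counts, TPM, ...); row names are sample ids.
#' @param grouping optional per-sample group labels (e.g. methylation
#'   groups).
#' @param tokens token budget each profile is rescaled to before fold-in
#'   (default 1e5).
#' @param sweeps fold-in Gibbs sweeps.
#' @param seed RNG seed.
#' @return list with `samples` (samples x topics weights, rows sum to 1)
#'   and `groups` (groups x topics contributions, rows sum to exactly 1;
#'   `NULL` without a grouping).
#' @export
transfer_topics_bulk <- function(model, bulk, grouping = NULL,
                                 tokens = 1e5, sweeps = 100, seed = 1) {
  stopifnot(inherits(model, "topic_model"), is.matrix(bulk) || inherits(bulk, "Matrix"))
  if (any(bulk < 0)) stop("bulk profiles must be non-negative")
  if (is.null(rownames(bulk))) {
    rownames(bulk) <- sprintf("sample_%03d", seq_len(nrow(bulk)))
  }
  shared <- intersect(model$vocabulary, colnames(bulk))
  report_dropped_genes(model$vocabulary, colnames(bulk),
                       "transfer_topics_bulk")
  if (!length(shared)) stop("no shared genes between model and bulk data")
  sub <- as.matrix(bulk[, shared, drop = FALSE])
  rs <- rowSums(sub)
  if (any(rs == 0)) stop("bulk profile(s) with no shared-gene signal")
  scaled <- round(sub / rs * tokens)
  scaled[rowSums(scaled) == 0, 1] <- 1  # guard against all-rounded-to-zero
  cm <- count_matrix(scaled)
  theta <- transfer_topics_cells(model, cm, sweeps = sweeps, seed = seed)
  groups <- NULL
  if (!is.null(grouping)) {
    stopifnot(length(grouping) == nrow(bulk))
    groups <- t(vapply(split(seq_len(nrow(theta)), grouping), function(idx) {
      v <- colMeans(theta[idx, , drop = FALSE])
      v / sum(v)
    }, numeric(ncol(theta))))
  }
  list(samples = theta, groups = groups)
}

#' Serialize and restore a topic model
#'
#' The model is written as two TSV matrices (`phi.tsv`, `theta.tsv`) plus
#' a JSON header (`model.json`) carrying K, the hyperparameters, the
#' vocabulary and an FNV-1a checksum of it.
#'
#' @param model a `topic_model`.
#' @param path directory to write into (created if needed).
#' @return `write_topic_model` returns `path` invisibly;
#'   `read_topic_model` returns the restored `topic_model`.
#' @export
write_topic_model <- function(model, path) {
  stopifnot(inherits(model, "topic_model"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  write.table(model$phi, file.path(path, "phi.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  write.table(model$theta, file.path(path, "theta.tsv"), sep = "\t",
              quote = FALSE, col.names = NA)
  header <- list(K = model$K, alpha = model$alpha, eta = model$eta,
                 iterations = model$iterations, seed = model$seed,
                 vocabulary = model$vocabulary,
                 vocabulary_hash = fnv1a(model$vocabulary))
  jsonlite::write_json(header, file.path(path, "model.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_topic_model
#' @export
read_topic_model <- function(path) {
  header <- jsonlite::read_json(file.path(path, "model.json"),
                                simplifyVector = TRUE)
  phi <- as.matrix(read.delim(file.path(path, "phi.tsv"), row.names = 1,
                              check.names = FALSE))
  theta <- as.matrix(read.delim(file.path(path, "theta.tsv"),
                                row.names = 1, check.names = FALSE))
  if (fnv1a(header$vocabulary) != header$vocabulary_hash) {
    stop("vocabulary checksum mismatch in ", path)
  }
  if (!identical(colnames(phi), header$vocabulary)) {
    stop("phi.tsv columns disagree with the stored vocabulary")
  }
  structure(list(K = as.integer(header$K), phi = phi, theta = theta,
                 vocabulary = header$vocabulary, alpha = header$alpha,
                 eta = header$eta, iterations = header$iterations,
                 seed = header$seed, loglik = numeric()),
            class = "topic_model")
}

#' Write a topic-gene ranking to per-topic TSV files
#'
#' @param ranking a [rank_topic_genes()] result.
#' @param path directory to write one `<topic>.tsv` per topic into.
#' @return `path`, invisibly.
#' @export
write_topic_ranking <- function(ranking, path) {
  stopifnot(inherits(ranking, "topic_gene_ranking"))
  dir.create(path, showWarnings = FALSE, recursive = TRUE)
  for (t in names(ranking)) {
    write.table(ranking[[t]], file.path(path, paste0(t, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(path)
}
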