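test_that("LDA fitting honours normalization, determinism and edge cases", {
  sim <- simulate_topic_corpus(3, 80, 60, 200, 0.1, seed = 50)
  fit <- fit_lda(sim$matrix, K = 3, iterations = 150, seed = 51)
  expect_equal(unname(rowSums(fit$phi)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(fit$theta)), rep(1, 60), tolerance = 1e-9)
  fit2 <- fit_lda(sim$matrix, K = 3, iterations = 150, seed = 51)
  expect_identical(fit$phi, fit2$phi)
  # K = 1 degenerates to the corpus distribution with unit weights
  one <- fit_lda(sim$matrix, K = 1)
  expect_equal(unname(one$theta[, 1]), rep(1, 60))
  expect_equal(unname(one$phi[1, ]),
               unname(colSums(as.matrix(sim$matrix$counts)) /
                        sum(sim$matrix$counts)))
  # empty documents are named in the error
  m <- tiny_counts(c(0L, 3L, 0L, 4L), 2, 2)
  expect_error(fit_lda(m, K = 2), "empty document.*c1")
})

test_that("a synthetic corpus is recovered topic-by-topic", {
  sim <- simulate_topic_corpus(3, 100, 200, 500, 0.1, seed = 52)
  fit <- fit_lda(sim$matrix, K = 3, iterations = 400, seed = 53)
  expect_gte(matched_cosine(sim$truth$phi, fit$phi), 0.9)
  # the collapsed chain's likelihood trends upward (10-sweep blocks):
  # every late block beats the opening block
  blocks <- colMeans(matrix(fit$loglik, nrow = 10))
  expect_gt(blocks[length(blocks)], blocks[1])
  expect_true(all(tail(blocks, 10) > blocks[1]))
})

test_that("gene rankings filter by specificity then sort by probability", {
  phi <- rbind(T1 = c(0.6, 0.2, 0.2), T2 = c(0.0, 0.5, 0.5))
  colnames(phi) <- c("gA", "gB", "gC")
  model <- structure(list(K = 2L, phi = phi / rowSums(phi),
                          theta = matrix(1, 1, 2), vocabulary = colnames(phi),
                          alpha = 1, eta = 0.1, iterations = 0, seed = 1,
                          loglik = numeric()),
                     class = "topic_model")
  r <- rank_topic_genes(model, 0.9)
  # gA is emitted by T1 only: specificity 1 there, absent from T2's list
  expect_equal(r$T1$gene, "gA")
  expect_equal(r$T1$specificity, 1)
  expect_equal(nrow(r$T2), 0L)
  # threshold 0 keeps everything as a pure probability sort
  r0 <- rank_topic_genes(model, 0)
  expect_equal(r0$T1$gene, c("gA", "gB", "gC"))
  expect_false(is.unsorted(rev(r0$T2$probability)))
  # a gene uniform across topics has specificity 1/K everywhere
  phiu <- rbind(T1 = c(0.5, 0.5), T2 = c(0.5, 0.5))
  colnames(phiu) <- c("u1", "u2")
  modelu <- model; modelu$phi <- phiu; modelu$vocabulary <- colnames(phiu)
  ru <- rank_topic_genes(modelu, 0)
  expect_equal(ru$T1$specificity, c(0.5, 0.5))
})

test_that("topic transfer recovers pure cells and renormalizes weights", {
  sim <- simulate_topic_corpus(3, 100, 150, 400, 0.1, seed = 54)
  fit <- fit_lda(sim$matrix, K = 3, iterations = 300, seed = 55)
  # target cells sampled purely from each true topic
  set.seed(63)
  pure <- t(vapply(1:3, function(k) {
    rmultinom(1, 500, sim$truth$phi[k, ])[, 1]
  }, integer(100)))
  dimnames(pure) <- list(sprintf("pure%d", 1:3), colnames(sim$truth$phi))
  w <- transfer_topics_cells(fit, count_matrix(pure), seed = 56)
  expect_equal(unname(rowSums(w)), rep(1, 3), tolerance = 1e-9)
  expect_true(all(apply(w, 1, max) >= 0.8))
  # distinct true topics map to distinct fitted topics
  expect_equal(length(unique(apply(w, 1, which.max))), 3L)
  # full-vocabulary transfer agrees with fit-time weights
  w_self <- transfer_topics_cells(fit, sim$matrix, seed = 57)
  expect_lt(mean(abs(w_self - fit$theta)), 0.05)
  # missing overlap errors
  alien <- tiny_counts(rep(1L, 4), 2, 2)
  expect_error(transfer_topics_cells(fit, alien), "no shared genes")
})

test_that("bulk transfer normalizes groups to exactly one", {
  sim <- simulate_topic_corpus(3, 100, 100, 300, 0.1, seed = 58)
  fit <- fit_lda(sim$matrix, K = 3, iterations = 300, seed = 59)
  pb <- rbind(s1 = sim$truth$phi[2, ] * 1e6,
              s2 = sim$truth$phi[2, ] * 1e6,
              s3 = sim$truth$phi[1, ] * 2e5)
  colnames(pb) <- colnames(sim$truth$phi)
  res <- transfer_topics_bulk(fit, pb, grouping = c("g1", "g1", "g2"),
                              seed = 60)
  expect_equal(unname(rowSums(res$samples)), rep(1, 3), tolerance = 1e-9)
  expect_equal(unname(rowSums(res$groups)), rep(1, 2), tolerance = 1e-12)
  # a pure-topic pseudobulk is dominated by one topic
  expect_gte(max(res$samples["s1", ]), 0.8)
  # identical samples give a group vector equal to either member's
  expect_equal(unname(res$groups["g1", ]),
               unname(res$samples["s1", ] / sum(res$samples["s1", ])),
               tolerance = 0.02)
})

test_that("models survive TSV + JSON serialization", {
  sim <- simulate_topic_corpus(2, 40, 20, 100, 0.5, seed = 61)
  fit <- fit_lda(sim$matrix, K = 2, iterations = 50, seed = 62)
  dir <- withr::local_tempdir()
  write_topic_model(fit, dir)
  back <- read_topic_model(dir)
  expect_equal(back$phi, fit$phi, tolerance = 1e-12)
  expect_equal(back$theta, fit$theta, tolerance = 1e-12)
  expect_equal(back$vocabulary, fit$vocabulary)
  # tampered vocabulary is caught by the checksum
  hdr <- jsonlite::read_json(file.path(dir, "model.json"),
                             simplifyVector = TRUE)
  hdr$vocabulary[1] <- "OTHER"
  jsonlite::write_json(hdr, file.path(dir, "model.json"), auto_unbox = TRUE)
  expect_error(read_topic_model(dir), "checksum")
  r <- rank_topic_genes(fit, 0.5)
  write_topic_ranking(r, dir)
  expect_true(file.exists(file.path(dir, "T1.tsv")))
})
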