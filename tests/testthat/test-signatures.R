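test_that("cell-cycle score is the UMI fraction of the gene set", {
  counts <- matrix(c(10L, 0L, 90L, 5L,   # g_cycle1
                     0L,  0L, 10L, 0L,   # g_cycle2
                     90L, 50L, 0L, 0L),  # g_other
                   nrow = 4,
                   dimnames = list(sprintf("c%d", 1:4),
                                   c("cyc1", "cyc2", "other")))
  m <- count_matrix(counts)
  s <- cell_cycle_score(m, c("cyc1", "cyc2"))
  expect_equal(unname(s), c(10 / 100, 0, 1, 1))
  # scale-free: tripling a cell's counts leaves its score unchanged
  m3 <- count_matrix(counts * 3L)
  expect_equal(cell_cycle_score(m3, c("cyc1", "cyc2")), s,
               ignore_attr = TRUE)
  # zero-total cells score 0 with a warning
  z <- count_matrix(rbind(counts, zero = c(0L, 0L, 0L)))
  expect_warning(sz <- cell_cycle_score(z, "cyc1"), "zero total")
  expect_equal(unname(sz[5]), 0)
})

test_that("cycling fraction uses a strictly-greater cutoff", {
  scores <- c(0.02, 0.01, 0.0, 0.5)
  expect_equal(unname(cycling_fraction(scores, rep("A", 4))), 50)
  expect_equal(unname(cycling_fraction(rep(0, 3), rep("B", 3))), 0)
  # size-weighted cluster values recover the global fraction under
  # randomized labels
  set.seed(1)
  s <- runif(400, 0, 0.05)
  cl <- sample(rep(letters[1:4], 100))
  per <- cycling_fraction(s, cl)
  sizes <- table(cl)[names(per)]
  expect_equal(sum(per * as.numeric(sizes)) / sum(sizes),
               mean(s > 0.01) * 100)
})

test_that("cluster enrichment matches the hand-computed formula", {
  counts <- matrix(c(2L, 4L, 0L, 0L,    # gene gA
                     1L, 1L, 1L, 1L,    # gene gB
                     0L, 0L, 3L, 5L),   # gene gC
                   nrow = 4,
                   dimnames = list(c("a1", "a2", "b1", "b2"),
                                   c("gA", "gB", "gC")))
  m <- count_matrix(counts)
  e <- cluster_enrichment(m, c("A", "A", "B", "B"))
  # hand calculation for gA in A: mean_in 3, mean_out 0, nnz 1 vs 0
  expect_equal(e$enrichment["A", "gA"],
               ((3 + 0.01) / 0.01) * ((1 + 0.01) / 0.01))
  # identical distribution -> enrichment 1 exactly
  expect_equal(unname(e$enrichment[, "gB"]), c(1, 1))
  expect_equal(e$ranking$A[1], "gA")
  expect_equal(e$ranking$B[1], "gC")
  expect_error(cluster_enrichment(m, rep("A", 4)), "at least two clusters")
})

test_that("top enriched genes agree with a brute-force sort", {
  set.seed(2)
  m <- tiny_counts(rpois(600, 2), 20, 30)
  cl <- rep(c("x", "y"), 10)
  e <- cluster_enrichment(m, cl)
  top <- top_enriched_genes(e, 5)
  for (c_ in c("x", "y")) {
    v <- e$enrichment[c_, ]
    brute <- names(sort(v, decreasing = TRUE))[1:5]
    # resolve ties as documented: lexicographic on gene id
    ord <- order(-v, names(v))
    expect_equal(top[[c_]], names(v)[ord][1:5])
    expect_setequal(top[[c_]], brute)
  }
})

test_that("signature score vanishes when the set is its own control", {
  set.seed(3)
  m <- tiny_counts(rpois(2000, 5), 40, 50)
  set <- gene_ids(m)[1:10]
  s <- signature_score(m, set, controls = set)
  expect_equal(unname(s), rep(0, 40), tolerance = 1e-12)
})

test_that("signature score is null-centred and recovers planted shifts", {
  set.seed(4)
  n_cells <- 500
  # null: an exchangeable matrix (every gene the same mean)
  flat <- matrix(rpois(n_cells * 400, 50), n_cells, 400,
                 dimnames = list(sprintf("c%03d", 1:n_cells),
                                 sprintf("g%03d", 1:400)))
  sig0 <- sample(colnames(flat), 40)
  null_s <- signature_score(count_matrix(flat), sig0,
                            signature_score_params(seed = 11))
  expect_lt(abs(mean(null_s)), 0.05)

  # shift: heterogeneous gene means, so expression bins reflect baseline
  # abundance rather than the planted perturbation
  n_genes <- 500
  lam <- exp(rnorm(n_genes, log(80), 0.5))
  base <- matrix(rpois(n_cells * n_genes, rep(lam, each = n_cells)),
                 n_cells, n_genes,
                 dimnames = list(sprintf("c%03d", 1:n_cells),
                                 sprintf("g%03d", 1:n_genes)))
  sig <- sample(colnames(base), 25)
  delta <- 0.5
  shifted_cells <- sample(n_cells, 100)
  shifted <- base
  shifted[shifted_cells, sig] <- round(base[shifted_cells, sig] * exp(delta))
  s2 <- signature_score(count_matrix(shifted), sig,
                        signature_score_params(seed = 11))
  recovered <- mean(s2[shifted_cells]) - mean(s2[-shifted_cells])
  expect_lt(abs(recovered - delta) / delta, 0.2)
})

test_that("permuting cell order permutes scores identically", {
  set.seed(5)
  m <- tiny_counts(rpois(1500, 8), 30, 50)
  sig <- gene_ids(m)[5:14]
  p <- signature_score_params(seed = 2)
  s <- signature_score(m, sig, p)
  perm <- sample(nrow(m$counts))
  s_perm <- signature_score(m[perm, ], sig, p)
  expect_equal(s_perm, s[perm])
})

test_that("driver sets are de-overlapped across cancers", {
  expect_equal(build_driver_sets(list(men = c("A", "B", "C"),
                                      gbm = c("C", "D"))),
               list(men = c("A", "B"), gbm = "D"))
  dis <- list(a = c("X", "Y"), b = c("Z"))
  expect_equal(build_driver_sets(dis), dis)
  same <- list(a = c("P", "Q"), b = c("P", "Q"))
  expect_equal(lengths(build_driver_sets(same)), c(a = 0L, b = 0L))
})
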