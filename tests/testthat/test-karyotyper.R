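make_selection_atlas <- function() {
  # 4 clusters x 120 genes; baseline 1.0 everywhere so each cluster's
  # 99th-percentile level is 1 and the pass threshold is 0.1
  genes <- sprintf("g%03d", 1:120)
  atlas <- matrix(1, 4, 120, dimnames = list(paste0("C", 1:4), genes))
  ann <- gene_annotation(data.frame(
    gene = genes,
    chrom = rep(c(as.character(1:22), "X", "Y"), length.out = 120),
    position = seq_len(120) * 1000))
  list(atlas = atlas, ann = ann, genes = genes)
}

test_that("gene selection keeps autosomal genes passing in >= half the clusters", {
  fx <- make_selection_atlas()
  atlas <- fx$atlas
  x_gene <- fx$ann$gene[fx$ann$chrom == "X"][1]
  two_of_four <- "g001"; one_of_four <- "g002"
  atlas[, two_of_four] <- c(0.5, 0.5, 0.05, 0.05)
  atlas[, one_of_four] <- c(0.5, 0.05, 0.05, 0.05)
  atlas[, x_gene] <- 5  # high everywhere, but X-linked
  kept <- select_genes(atlas, fx$ann)
  expect_true(two_of_four %in% kept)
  expect_false(one_of_four %in% kept)
  expect_false(x_gene %in% kept)
  # output ordered along the genome: (chromosome, position)
  ann_kept <- attr(kept, "annotation")
  key <- order(match(ann_kept$chrom, c(as.character(1:22), "X", "Y")),
               ann_kept$position)
  expect_equal(key, seq_len(nrow(ann_kept)))
  expect_equal(kept, ann_kept$gene, ignore_attr = TRUE)
  # too few survivors is an explicit error
  low <- atlas * 0.001
  low[, 1:10] <- 1
  expect_error(select_genes(low, fx$ann), "survive selection")
})

test_that("cells are normalized to the median total", {
  m <- tiny_counts(c(10L, 20L, 40L, 10L, 20L, 40L), 3, 2)
  norm <- normalize_cells(m)
  expect_equal(unname(rowSums(norm)), rep(40, 3))  # median total = 40
  equal <- tiny_counts(rep(5L, 6), 3, 2)
  expect_equal(normalize_cells(equal), as.matrix(equal$counts))
})

test_that("reference matching is exact on clean profiles and robust to noise", {
  ref <- generate_reference_atlas(4, 1000, seed = 31)
  kept <- select_genes(ref$atlas, ref$annotation)
  match1 <- match_reference(ref$atlas["C2", , drop = FALSE] * 3,
                            ref$atlas, kept)
  expect_equal(unname(match1), "C2")
  sim <- simulate_cells(ref$atlas, ref$annotation, 150, depth = 10000,
                        seed = 32)
  matches <- match_reference(normalize_cells(sim$matrix), ref$atlas, kept)
  expect_gte(mean(matches == sim$truth$cluster), 0.99)
  flat <- matrix(1, 1, 1000, dimnames = list("flat", colnames(ref$atlas)))
  expect_error(match_reference(flat, ref$atlas, kept),
               "correlation undefined")
})

test_that("ploidy tracks are exact on deterministic inputs", {
  ref <- generate_reference_atlas(3, 1200, seed = 33)
  kept <- select_genes(ref$atlas, ref$annotation)
  ann <- attr(kept, "annotation")
  # cell identical to its reference: every track value exactly 2
  cellv <- ref$atlas["C1", , drop = FALSE]
  rownames(cellv) <- "cell"
  pt <- ploidy_tracks(cellv, ref$atlas, c(cell = "C1"), kept)
  expect_equal(unname(pt$tracks[1, ]), rep(2, length(kept)))
  # one chromosome scaled 1.5x: smoothed interior 3, elsewhere 2
  target <- "7"
  cellv2 <- cellv
  cellv2[, colnames(cellv) %in% ann$gene[ann$chrom == target]] <-
    cellv2[, colnames(cellv) %in% ann$gene[ann$chrom == target]] * 1.5
  pt2 <- ploidy_tracks(cellv2, ref$atlas, c(cell = "C1"), kept)
  idx <- which(ann$chrom == target)
  h <- 12  # half-window of the default 25-gene smoother
  interior <- idx[(h + 1):(length(idx) - h)]
  expect_equal(unname(pt2$tracks[1, interior]),
               rep(3, length(interior)))
  other <- which(!ann$chrom %in% target)
  expect_equal(unname(pt2$tracks[1, other]), rep(2, length(other)))
  # window wider than a chromosome: whole-chromosome mean, no error
  small <- karyotyper_params(smoothing_window = 10000)
  pt3 <- ploidy_tracks(cellv2, ref$atlas, c(cell = "C1"), kept, small)
  expect_equal(unname(unique(round(pt3$tracks[1, idx], 12))), 3)
})

test_that("median recentring pins every smoothed track at 2", {
  ref <- generate_reference_atlas(3, 1000, seed = 34)
  sim <- simulate_cells(ref$atlas, ref$annotation, 30, depth = 8000,
                        seed = 35)
  kept <- select_genes(ref$atlas, ref$annotation)
  norm <- normalize_cells(sim$matrix)
  matches <- match_reference(norm, ref$atlas, kept)
  pt <- ploidy_tracks(norm, ref$atlas, matches, kept)
  meds <- apply(pt$tracks, 1, median, na.rm = TRUE)
  expect_equal(unname(meds), rep(2, 30))
})

test_that("metacells separate clones and are deterministic", {
  ref <- generate_reference_atlas(4, 1500, seed = 36,
                                  chromosomes = as.character(1:22))
  clones <- list(cna_spec("del22", 0.5, c("22" = 1, "3" = 3)))
  sim <- simulate_cells(ref$atlas, ref$annotation, 200, clones,
                        depth = 10000, seed = 37)
  kept <- select_genes(ref$atlas, ref$annotation)
  norm <- normalize_cells(sim$matrix)
  matches <- match_reference(norm, ref$atlas, kept)
  pt <- ploidy_tracks(norm, ref$atlas, matches, kept)
  mc <- metacells(pt, seed = 38)
  expect_identical(mc, metacells(pt, seed = 38))
  # >= 95% of cells share their metacell with their own clone's majority
  purity <- vapply(split(sim$truth$clone, mc), function(cl) {
    max(table(cl)) / length(cl)
  }, numeric(1))
  sizes <- vapply(split(sim$truth$clone, mc), length, numeric(1))
  expect_gte(sum(purity * sizes) / sum(sizes), 0.95)
  # identical cells collapse to a single metacell
  one <- pt
  one$tracks <- matrix(2, 40, ncol(pt$tracks),
                       dimnames = list(sprintf("c%d", 1:40),
                                       colnames(pt$tracks)))
  expect_equal(unname(unique(metacells(one, seed = 1))), 1L)
})

test_that("the Viterbi segmentation matches nearest-state intuition", {
  ann <- data.frame(gene = sprintf("g%d", 1:60),
                    chrom = rep(c("1", "2"), each = 30),
                    position = rep(1:30, 2))
  track <- c(rep(1.02, 30), rep(2.0, 30))
  segs <- call_copy_numbers(track, ann)
  expect_equal(nrow(segs), 2L)
  expect_equal(segs$copy, c(1L, 2L))
  expect_equal(segs$n_genes, c(30L, 30L))
  all2 <- call_copy_numbers(rep(2, 60), ann)
  expect_true(all(all2$copy == 2))
})

test_that("Viterbi agrees with exhaustive path enumeration", {
  set.seed(40)
  for (i in 1:50) {
    n <- sample(2:8, 1)
    obs <- runif(n, -0.5, 3.5)
    fast <- hmm_viterbi(obs, max_copies = 3, emission_sd = 0.3,
                        stay_probability = 0.999)
    slow <- brute_force_viterbi(obs, max_copies = 3, emission_sd = 0.3,
                                stay_prob = 0.999)
    expect_identical(fast, slow)
  }
})

test_that("karyotype calls are invariant to a global scale factor", {
  ref <- generate_reference_atlas(3, 800, seed = 41)
  sim <- simulate_cells(ref$atlas, ref$annotation, 60,
                        list(cna_spec("gain9", 0.5, c("9" = 3))),
                        depth = 8000, seed = 42)
  kt1 <- karyotype(sim$matrix, ref$atlas, ref$annotation, seed = 43)
  m3 <- count_matrix(as.matrix(sim$matrix$counts) * 3L)
  kt3 <- karyotype(m3, ref$atlas, ref$annotation, seed = 43)
  expect_identical(chromosome_copy_matrix(kt1), chromosome_copy_matrix(kt3))
  expect_equal(kt1$metacell, kt3$metacell, ignore_attr = TRUE)
})

test_that("diploid cells yield diploid calls and clones are recovered", {
  ref <- generate_reference_atlas(4, 1500, seed = 44,
                                  chromosomes = as.character(1:22))
  sim0 <- simulate_cells(ref$atlas, ref$annotation, 120, depth = 10000,
                         seed = 45)
  kt0 <- karyotype(sim0$matrix, ref$atlas, ref$annotation, seed = 46)
  expect_true(all(chromosome_copy_matrix(kt0) == 2))
  clone <- cna_spec("mut", 1 / 3, c("22" = 1, "9" = 3))
  sim <- simulate_cells(ref$atlas, ref$annotation, 180, list(clone),
                        depth = 10000, seed = 47)
  kt <- karyotype(sim$matrix, ref$atlas, ref$annotation, seed = 48)
  cmp <- expected_chromosome_calls(kt, sim$truth,
                                   list(mut = c("22" = 1, "9" = 3)))
  expect_gte(mean(cmp$called == cmp$expected), 0.95)
})
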