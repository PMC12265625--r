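# Shared fixture builders and small independent oracles.

# A tiny count matrix with explicit values.
tiny_counts <- function(values, n_cells, n_genes, meta = NULL) {
  m <- matrix(values, n_cells, n_genes,
              dimnames = list(sprintf("c%d", seq_len(n_cells)),
                              sprintf("g%d", seq_len(n_genes))))
  count_matrix(m, meta)
}

cosine <- function(a, b) sum(a * b) / sqrt(sum(a^2) * sum(b^2))

# Best mean cosine between matched rows of two K x G matrices over all
# K! permutations (K small).
matched_cosine <- function(true_phi, fit_phi) {
  K <- nrow(true_phi)
  perms <- function(v) {
    if (length(v) == 1) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1]] <- c(v[i], rest)
    }
    out
  }
  best <- -Inf
  for (p in perms(seq_len(K))) {
    s <- mean(vapply(seq_len(K), function(k) {
      cosine(true_phi[k, ], fit_phi[p[k], ])
    }, numeric(1)))
    best <- max(best, s)
  }
  best
}

# Exhaustive-enumeration oracle for the copy-number HMM: scores every
# state path and returns the best (ties resolved toward the path that is
# smaller in left-to-right state order, matching Viterbi's lower-state
# preference).
brute_force_viterbi <- function(obs, max_copies, emission_sd, stay_prob) {
  states <- 0:max_copies
  S <- length(states)
  n <- length(obs)
  paths <- as.matrix(expand.grid(rep(list(seq_len(S)), n)))[, n:1, drop = FALSE]
  emis <- matrix(0, S, n)
  for (t in seq_len(n)) {
    if (!is.na(obs[t])) {
      emis[, t] <- dnorm(obs[t], states, emission_sd, log = TRUE)
    }
  }
  lp <- rep(log(1 / S), nrow(paths))
  for (t in seq_len(n)) lp <- lp + emis[cbind(paths[, t], t)]
  if (n > 1) {
    for (t in 2:n) {
      stayed <- paths[, t] == paths[, t - 1]
      lp <- lp + ifelse(stayed, log(stay_prob), log((1 - stay_prob) / (S - 1)))
    }
  }
  best <- max(lp)
  cand <- which(lp >= best - 1e-12)
  # deterministic tie-break: lexicographically smallest state sequence
  if (length(cand) > 1) {
    key <- apply(paths[cand, , drop = FALSE], 1, paste, collapse = ",")
    cand <- cand[order(key)][1]
  }
  states[paths[cand, ]]
}

# Expected karyotype of a metacell given the clone truth of its members:
# the majority clone's events over otherwise-diploid autosomes.
expected_chromosome_calls <- function(kt, truth, clone_events) {
  cm <- chromosome_copy_matrix(kt)
  exp_cm <- cm
  exp_cm[] <- 2L
  for (mc in rownames(cm)) {
    members <- names(kt$metacell)[kt$metacell == mc]
    major <- names(sort(table(truth$clone[truth$cell %in% members]),
                        decreasing = TRUE))[1]
    if (major %in% names(clone_events)) {
      ev <- clone_events[[major]]
      for (ch in names(ev)) exp_cm[mc, ch] <- ev[[ch]]
    }
  }
  list(called = cm, expected = exp_cm)
}
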