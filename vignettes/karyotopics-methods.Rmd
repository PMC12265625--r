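---
title: "Models and methods behind karyotopics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind karyotopics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(karyotopics)
```

`karyotopics` bundles the computational stack used to analyse developing
meninges and meningeal tumours from UMI count data: expression-based
copy-number inference, LDA gene programs with cross-platform transfer,
control-matched signature scoring, layer-maturation assignment, and
two-round quality control. This vignette explains each model, its
assumptions and tunable parameters, what the synthetic generators emulate,
and the numerical decisions taken where the design was open.

## Expression-based karyotyping

### Model

A chromosome-scale copy-number change multiplies the expected expression
of the affected genes by `copy / 2` relative to a diploid cell of the same
type. Karyotyping therefore reduces to estimating, per cell, the ratio of
observed to expected expression along the genome — provided "expected"
comes from a trustworthy diploid reference. Using an external atlas of
normal cluster profiles avoids having to identify normal cells inside the
tumour sample itself.

The steps, each exposed as its own function:

1. **Gene selection** (`select_genes`): keep autosomal genes expressed
   above `expr_fraction_of_quantile` (0.10) times the cluster's
   `expr_quantile` (0.99) expression level in at least
   `min_cluster_fraction` (half) of the atlas clusters. Low-expression
   genes make the ratio estimator unstable; sex chromosomes are excluded
   because donor sex differences masquerade as CNAs. The quantile is
   computed within each cluster; `pooled_quantile = TRUE` switches to a
   single pooled threshold.
2. **Depth normalization** (`normalize_cells`): each cell is scaled to
   the median total UMI count. Any global scaling of the counts cancels
   here, which is the root of the pipeline's scale invariance.
3. **Reference matching** (`match_reference`): Pearson correlation over
   the kept genes against every atlas profile; the argmax cluster is the
   cell's expected expression. Ties break lexicographically; constant
   cell vectors are rejected (correlation undefined).
4. **Ploidy tracks** (`ploidy_tracks`): `2 * cell / reference` per gene,
   a centered 25-gene rolling mean within each chromosome (windows
   truncate at chromosome boundaries — no cross-chromosome bleed), then
   the track is rescaled so its genome-wide median is exactly 2. The
   recentring absorbs the compositional effect of losing or gaining
   chromosomes (losing chr22 inflates every other gene's share of the
   cell's UMIs). Genes whose matched reference value is below `1e-9` are
   masked from the track: the ratio is undefined there, and a pseudocount
   would fabricate ploidy.
5. **Metacells** (`metacells`): PCA (centred, unscaled) to `n_pcs = 5`,
   a mutual k-nearest-neighbour graph (`knn = 30`; an edge survives only
   if each endpoint lists the other), Leiden clustering (modularity,
   resolution 1, seeded). Mutual graphs separate clones cleanly but can
   isolate single noisy cells as singleton communities, which would then
   be called without any averaging; metacells smaller than
   `min_metacell_size = 5` are therefore folded into the nearest larger
   metacell by PC-centroid distance.
6. **Copy-number calling** (`call_copy_numbers`): per chromosome, a
   hidden Markov model over integer states `0..max_copies` (6), Gaussian
   emissions centred on the state with `emission_sd = 0.3` ploidy units,
   uniform initial distribution, and `stay_probability = 0.999` on the
   transition diagonal, decoded by the Viterbi algorithm on the
   metacell's mean track.

### Numerical choices

The HMM parameters are the package's own defaults: 0.3 ploidy units is
wide enough that a single 25-gene window cannot flip a call on its own,
while a run of windows at the scale of the smoothing window can; a stay
probability of 0.999 prices one transition at roughly seven units of
log-likelihood, matching that intent. States run to six copies because
high-level amplifications beyond that are rare at chromosome scale and
would saturate the ratio estimator anyway. Viterbi ties prefer the lower
copy number, and the implementation is checked against exhaustive path
enumeration in the test suite. All of these are configurable through
`karyotyper_params()`.

### Assumptions and limitations

The method assumes the reference atlas contains a profile close to each
cell's normal counterpart, that CNAs are chromosome-scale or at least
span tens of adjacent expressed genes, and that expression scales
linearly with copy number in expectation. Focal events smaller than the
smoothing window, copy-neutral loss of heterozygosity, and dosage
compensation are invisible to it. No allele or SNP evidence is used.

## LDA topics and transfer

`fit_lda()` runs collapsed Gibbs sampling over token–topic assignments
with symmetric priors (`alpha = 50/K` on document mixtures, `eta = 0.1`
on topic–gene distributions, 1000 sweeps by default, seeded); point
estimates for both matrices are read off the final sampler state, and a
per-sweep token log-likelihood is recorded as a convergence monitor. Raw
counts are used — LDA consumes tokens, and any transformation would break
its generative semantics. `K = 1` is handled as the degenerate corpus
distribution; the study-scale default is `K = 35`.

Representative genes per topic (`rank_topic_genes`) are filtered by
*specificity* — the gene's probability in the topic divided by its
probability summed across topics — then sorted by unnormalized
probability. The specificity threshold is a required, deliberately
defaulted-nowhere parameter: it is a reporting choice, not a model
constant.

Transfer (`transfer_topics_cells`, or `predict()` on the model) restricts
the topic–gene matrix to genes shared with the target (renormalizing each
topic, reporting dropped genes; matching is exact and case-sensitive) and
infers weights by fold-in Gibbs with the topics frozen (100 sweeps,
seeded). Fold-in is the standard mechanism for scoring new documents
against a fitted model and is invariant, in expectation, to scaling a
target cell's counts. Bulk profiles (`transfer_topics_bulk`) are treated
as single documents: each profile is rescaled to a 100,000-token budget —
bounding runtime and accommodating non-integer units such as TPM — folded
in, averaged within groups, and renormalized so each group's
contributions sum to exactly 1. Per-sample normalization happens before
group averaging. Discarding quality-driven or uninterpretable topics is a
manual decision; the CLI exposes an explicit exclusion list and nothing
is dropped automatically.

## Signature scoring with matched controls

Scores are computed on log-normalized expression (counts scaled to 10,000
per cell, then `log(1 + x)` — the same convention the spatial processing
uses). Each gene is centred by its mean across cells; genes are ranked by
aggregate expression and cut into `n_bins = 25` equal-size bins; for each
signature gene, `n_controls_per_gene = 100` controls are drawn with
replacement from its bin (excluding the gene itself, seeded). The score
is the mean relative expression over the signature minus the mean over
the pooled controls, so depth and per-gene baseline effects cancel and a
bin-matched random set scores zero in expectation.

One consequence of bin matching is worth knowing: if the background
matrix is perfectly exchangeable (every gene the same mean), any planted
perturbation *itself* determines the bin order, the perturbed genes
become each other's controls, and the score cancels. On realistic data,
bins are driven by baseline abundance differences that dwarf
biological shifts, and planted shifts are recovered; the tests exercise
both regimes.

`cell_cycle_score()` is simpler by design — the fraction of a cell's
UMIs falling in a set of known cycle genes — making it scale-free and
robust at low depth. `cycling_fraction()` reports the percentage of
cells per cluster strictly above a 0.01 score.
`cluster_enrichment()` multiplies a mean-expression ratio and a
detection-fraction ratio (each stabilized with `eps = 0.01`) between a
cluster and all others pooled; the exact formula of the framework it
mirrors is unpublished, so ours is validated against its own hand
oracle and used only for ranking.

## Layer maturation

Fetal fibroblasts are labelled by resemblance to adult meningeal layers
using the top 50 enriched genes per layer, filtered to maturation genes:
a gene detected (count ≥ 1) in more than 15% of early-group cells
(post-conceptional weeks 5–6, by default the two earliest timepoints) is
removed. Within a cell, a set gene counts as expressed only above a raw
count of 2 (strictly), and the cell takes the layer with the highest
expressed-gene fraction provided it reaches 5%, otherwise "Other". When
two layers tie on that fraction the earlier layer in the supplied list
wins (list layers pia, arachnoid, dura for the anatomical
outside-in priority); ties are logged. Competition uses the
expressed-gene *fraction* rather than summed expression — fractions are
robust to single high-count genes and match the 5% criterion's own
units. Reported per timepoint are label fractions (summing to 1) and the
median over cells of the mean raw count across each filtered set.

## Quality control

Round 1 (`filter_cells`) removes cells with fewer than 1000 UMIs,
unspliced fraction below 0.1, or a doublet score at or above 0.4.
"Fewer/less than" are strict `<`; "at least" is `≥`. The doublet
direction deserves a note: the thresholds' source text reads "a doublet
score below 0.4 were removed", which contradicts DoubletFinder-style
semantics where high scores mark doublets. The default removes high
scores; `doublet_direction = "low"` reproduces the literal reading. Every
failing criterion is enumerated in per-cell reason codes, and filters are
idempotent. Round 2 (`filter_clusters`) removes clusters in which at
least 40% of cells fall under 1800 UMIs; it is applied after round 1, on
the pooled clustered build. Manual removals (doublet-looking clusters,
haemoglobin contamination) are judgment calls, not algorithms, and are
out of scope.

Spatial transcript tables keep only nucleus-assigned transcripts
(discarding many reads but minimising segmentation errors), tabulate
cell × gene counts, drop cells under 8 genes / 20 transcripts (fetal
tissue) or 3 / 5 (tumours), and normalize kept cells to 10,000 counts
followed by `log(1 + x)`; raw and normalized layers are both retained.

## The synthetic-data module

The generators define the conditions under which the pipeline is tested;
they are first-class, seeded, pure functions of their arguments.

* `generate_reference_atlas()` draws cluster profiles i.i.d. from a
  log-normal prior (meanlog 0, sdlog 1) and apportions genes to
  chromosomes 1–22, X, Y proportionally to real per-chromosome gene
  counts (a hard-coded table; largest-remainder rounding), with strictly
  increasing positions.
* `simulate_cells()` draws Poisson counts around cluster means scaled by
  `copy / 2` on affected chromosomes and renormalized to the requested
  depth (default 10,000 UMIs per cell, the study's scale). Clone sizes
  are deterministic rounded fractions, so group comparisons are exact. An
  optional negative-binomial dispersion adds over-dispersion; the default
  is plain Poisson, the simplest noise model under which the ratio
  estimator is unbiased.
* `simulate_topic_corpus()` performs standard LDA generative draws
  (topics from Dirichlet(0.1), mixtures from Dirichlet(alpha)) and
  returns the true distributions.
* `simulate_layer_gradient()` gives each layer a signature whose
  expression probability rises monotonically with timepoint (quadratic
  ramp from 4% to 90% in the cell's own layer, a weak linear background
  ramp from 1% to 19% elsewhere), with "on" counts of 3 + Poisson(3) in
  the own layer so the count-above-2 rule fires, faint 1 + Poisson(1)
  leak otherwise, and 200 unstructured background genes. The two
  earliest timepoints (mapped to PCW 5 and 6) detect signature genes in
  well under 15% of cells, so the signatures survive the early filter.
* `generate_qc_fixture()` emits the full 3 × 3 × 3 grid of cells at the
  QC boundaries (999/1000/1001 UMIs, 0.09/0.10/0.11 unspliced,
  0.39/0.40/0.41 doublet) with truth flags under the documented rule.

What the generators deliberately do not emulate: ambient RNA and doublet
mixtures, per-gene over-dispersion structure, spliced/unspliced kinetics,
batch effects, spatial geometry beyond a flat transcript table, and
reference atlases that imperfectly match the sample. Passing tests
therefore demonstrate correctness of the algorithms under their stated
model, not robustness to every artefact of real tissue.

## Problem sizes and determinism

The shipped tests and the acceptance script run at desk scale, chosen so
each check finishes in seconds while keeping the estimators in their
asymptotic regime: karyotyping uses 4-cluster atlases over 2,200
autosomal genes with 200 diploid plus 100 clone cells at depth 10,000
(ten replicate simulations); topic recovery uses a 3-topic corpus of 200
documents × 500 tokens over a 100-gene vocabulary; signature checks use
500 cells; maturation uses 3 layers × 4 timepoints × 150 cells per
group. Every stochastic step takes an explicit seed, and all generators
are bit-reproducible for a fixed seed. Viterbi decoding is checked
exactly against exhaustive enumeration on short tracks; on constant
tracks the nearest state always wins, and the genome-wide median of
every smoothed ploidy track is exactly 2 by construction.

## Known limitations

Reference-free operation is not supported: karyotyping quality is bounded
by atlas fidelity. The LDA sampler is single-chain; multi-modal
posteriors are resolved only through the seed. Bulk transfer treats each
profile as one document and so ignores within-sample heterogeneity
beyond the topic mixture. The maturation score assumes layer signatures
are sufficiently disjoint after filtering; heavily overlapping signatures
degrade to the tie-break. The CLI covers the pipeline's stages but is a
thin convenience layer — the R functions are the primary interface.
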