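---
title: "Methods: community structure and ecosystem-function stability"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: community structure and ecosystem-function stability}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(microstab)
```

## The problem

Dilution-to-extinction experiments inoculate sterilized soil with serially
diluted suspensions of a source community. Dilution strips rare taxa, so
the treatments span a controlled α-diversity gradient while biomass
recovers during regrowth. Exposing these microcosms to a stressor and
measuring microbial-mediated process rates asks two questions: does
ecosystem function lose stability as diversity falls, and *which*
community property — α diversity, membership, biomass, a functional
guild — statistically drives each function? `microstab` implements the
full analysis chain for such designs and a synthetic generator for
validating it end to end.

The data model is three tables joined on sample id: an ASV count table
with taxonomy, sample metadata (land use, ordered diversity level
D0 < D1 < D2, stress, replicate), and a per-sample table of covariates
(biomass, qPCR gene abundances, mean 16S operon number) and process
measurements. All files are UTF-8 TSV with `#`-prefixed header comments
carrying units, so fixtures stay reviewable in diffs. Count matrices are
accepted taxa-as-rows (the common amplicon convention) and normalized
internally to samples × taxa. Missing values are an explicit `NA`, never a
silent zero; each stage documents whether it drops or rejects them.

## Repeated-rarefaction diversity

Unequal sequencing depth biases richness and Shannon comparisons.
`repeated_rarefaction()` subsamples each sample to a common depth without
replacement (multivariate hypergeometric; implemented by drawing
individual indices and binning through cumulative counts, so no
individual-level vector is materialized) and averages the Shannon index
and observed richness over `n_iter` independent draws (default 1000).

Choices worth knowing:

- **Log base.** Shannon is reported in natural log (nats) by default;
  `base = 2` switches to bits. The base is recorded in the result's
  attributes.
- **Depth.** Default is the smallest retained sample total; override it
  when a rarefaction curve (`rarefaction_curve()`) shows a better
  plateau. Samples below the depth are excluded with a warning and listed
  in the result — exclusions propagate through downstream joins rather
  than erroring the run.
- **Per-iteration metrics.** Metrics are computed on each rarefied draw
  and then averaged (not computed once on an averaged table); that is the
  convention of the repeated-rarefaction approach and gives an honest
  Monte-Carlo sd per sample.
- **Determinism.** Every draw is seeded from (seed, sample id,
  iteration), so results are bit-reproducible and invariant to sample
  order. The closed form `expected_rarefied_richness()` (hypergeometric
  absence probabilities) is the analytic reference the estimator is
  tested against.

## RC_Bray: null-model standardized dissimilarity

Bray–Curtis dissimilarity is confounded with α diversity: two samples of
very different richness look dissimilar even if assembled from the same
pool. The Raup–Crick standardization compares the observed Bray–Curtis of
a pair to dissimilarities between *null* communities with each sample's
richness S and total abundance N held fixed.

The literature describes the null model's intent but implementations vary
in the assembly details; the scheme here is the two-step
occurrence-then-abundance procedure of the abundance-based Raup–Crick
lineage, stated explicitly because it is the module's core interpretive
decision:

1. Draw S distinct taxa from the regional pool *without replacement*,
   selection probability proportional to occurrence frequency (the
   fraction of samples containing the taxon). Implemented with
   exponential keys (`rexp(1)/w`, keep the S smallest), which is
   distributionally identical to sequential weighted draws but
   vectorized.
2. Place one individual in each drawn taxon, then distribute the
   remaining N − S individuals multinomially with probability
   proportional to pooled relative abundance.

Each of `n_null` iterations (default 1000) assembles both members of the
pair independently; with α the fraction of null Bray–Curtis values below
the observed (values within `tie_tol = 1e-10` counted half — exact
floating-point equality would be meaningless), RC = 2α − 1. The diagonal
of an RC matrix is −1: a sample is maximally "more similar than expected"
to itself. Pairs get deterministic seed substreams keyed by sorted sample
ids, so the matrix is symmetric by construction, reproducible, and
invariant to row order; pair-level parallelism would change nothing.

The **regional pool** defaults to all samples in the table; pass `pool =
null_pool(subset)` to restrict it to a metadata-defined group. Pooling
across the whole experiment is the default because the dilution treatments
share a source community; per-land-use pools are a defensible alternative
the interface leaves open.

Validation is oracle-based: on a 3-taxon instance with S = N = 2 the null
outcome space is small enough to enumerate exactly, and the Monte-Carlo RC
must match the enumerated value within binomial error; exchangeable pairs
(both members drawn from the null itself) must center near RC = 0.

## Ordination and PERMANOVA

`pcoa()` is classical scaling: double-center −½·J·D²·J, eigendecompose,
scale eigenvectors by √λ for positive eigenvalues. Negative eigenvalues
are reported (as `negative_mass`), not corrected — no Lingoes/Cailliez
adjustment is applied by default, so users can judge distortion instead of
silently absorbing it. RC matrices are not metric and carry −1 diagonals;
before embedding, the minimum off-diagonal value is subtracted and the
diagonal zeroed. This monotone shift preserves the rank order of
dissimilarities and is recorded in the result (`shift`). The first k = 3
axes are exported as predictors `PCoA1..3` by default (`pcoa_axes` in
`run_config()`): enough to capture the land-use and dilution axes in this
design without flooding the forest with near-noise axes.

`permanova()` partitions the trace of the Gower-centered matrix
sequentially over the model terms (so term R² plus residual R² sums to 1),
with significance by free permutation of sample rows:
p = (1 + #(F\* ≥ F)) / (1 + n_perm), one-sided and never exactly zero. It
is tested for exact F/R² agreement with `vegan::adonis2(..., by =
"terms")` and for type-I error calibration under label permutation.
Restricted permutation (strata) is out of scope.

## Derived processes, multifunctionality, resistance

- qCO₂ = respiration/biomass; higher = less carbon-use efficient. No
  inversion is applied — interpretation is left to reporting.
- Net N mineralization = Δ(NH₄-N + NO₃-N)/days; net nitrification =
  Δ(NO₃-N)/days. Negative rates are biologically meaningful
  (immobilization, NO₃ consumption) and are never truncated.
- Total enzyme activity is the sum of the four hydrolase rates; `NA`
  propagates.
- Multifunctionality is the per-sample mean of z-scaled functions. The
  z-scale uses the sample (n−1) sd by default (`sd_type = "population"`
  switches); a zero-variance function is an error naming the function.
  The index is invariant to affine rescaling of any input, so units never
  matter.

The resistance index is RS = 1 − 2|D₀|/(|C₀| + |D₀|). **D₀ is the
control-minus-stressed difference** (D₀ = C₀ − P₀): under this reading
RS = 1 exactly when stress leaves the function unchanged and RS → −1 as
|D₀|/C₀ → ∞, which is the only reading consistent with the index's
defining property. |C₀| (rather than C₀) keeps the index defined for
functions whose control mean is legitimately negative, such as net N
rates. C₀ and P₀ are within-cell (land use × diversity) means;
`mode = "replicate"` instead scores each stressed replicate against the
control mean, giving replicate-level values for error bars — the pairing
of stressed replicates to controls is otherwise arbitrary, so both modes
are provided.

## Random-forest importance

The forest learner is `randomForest`; the tuning loop and the importance
procedure are this package's own. Three decisions define the procedure:

- **Model error is always out-of-bag.** Each sample is predicted only by
  trees whose bootstrap excluded it, for tuning and importance alike.
  Evaluating a shuffled predictor in-bag would reward overfitting.
- **Tuning.** mtry (candidates per split) is scanned over 1..P with a
  fixed per-value seed; the final forest is refit at the OOB-MSE
  minimizer, ties to the smallest value. The trace is kept in the result.
- **Importance = mean increase in OOB MSE after shuffling one predictor's
  column across the whole data set** (others fixed), over `n_shuffles`
  independent permutations (default 30; the repetition count is a
  Monte-Carlo smoothing choice, not a model parameter). Raw, possibly
  negative, importances are retained; ranks clamp at zero.

Default `n_trees` is 10,000 — at that size the forest's Monte-Carlo noise
is negligible; the tests run at 100–500 trees because tree count affects
only that noise, and the recovery properties are already stable there.
Candidate predictors follow a response-specific scheme: nitrifier (AOA,
AOB) abundances join the set only for nitrification; an alternative
variant appends genus-level relative abundances. The module is validated
by parameter recovery: when the generator plants nitrification on
nitrifier abundance and respiration on biomass, those predictors must
attain rank 1 across seeded runs while richness and Shannon must not —
the central inferential pattern this analysis exists to support — and a
pure-noise predictor's importance must center on zero.

## The synthetic generator

`simulation_scenario()` defaults describe the reference design: 2 land
uses × 3 dilution levels × 2 stress levels × 5 replicates (60 samples).
Per land use a lognormal taxon pool (400 taxa, sdlog 1.8, 25% shared
between land uses) is sampled by each microcosm as a multinomial draw of
the level's inoculum cell count (10⁶/10³/10² for D0/D1/D2); survivors
regrow with lognormal noise (sdlog 0.5) — the simplest mechanism by which
biomass recovers while richness does not — and sequencing counts are
drawn at a negative-binomial depth (mean 2×10⁴). Guilds tagged on fixed
pool fractions (25% stress-sensitive, 10% stress-tolerant, 5% nitrifier)
receive their multipliers (0.15×, 3×, 0.72×) *only in stressed D2
samples*, so stress responses are confined to the lowest-diversity
treatment; biomass is inflated 1.69× there. Functions are stated linear
maps of planted drivers plus Gaussian noise — respiration on biomass, SIR
on a designated copiotroph genus's relative abundance, nitrification on
AOA+AOB abundance, enzymes and N mineralization on biomass and a latent
membership gradient — with noise sds chosen so each named driver explains
roughly 70–99% of its response's variance, the regime in which driver
recovery is the designed behavior. Inorganic-N pools at two time points
are back-computed from the planted rates so the processes module recovers
them exactly. Ground truth (guilds, coefficients, seed) is emitted with
every simulation.

With these defaults the realized richness gradient steps down by ~54%
(D0→D1) and ~71% (D1→D2). The second step is steeper than the ~45% of
published dilution gradients: a 100-cell inoculum hard-caps richness near
60 observed taxa, and no single-lognormal pool can soften that step while
keeping the first one realistic. A two-component (abundant + rare) pool
could, at the cost of a more complicated scenario surface; the
single-lognormal pool was kept and the steeper step accepted, since every
analysis property exercised here depends on the ordering and spread of
the gradient, not the exact step sizes.

What the generator does **not** emulate — and therefore what passing
tests do not show about real data: no fungal community (only an ITS
covariate collapsing in diluted treatments, mirroring establishment
failure); no temporal dynamics of stressor degradation or recovery; no
compositional coupling between taxa beyond the shared multinomial; taxa
are exchangeable within guilds, unlike real phylogenetically structured
responses; and C mineralization responds to stress through the planted
biomass inflation, whereas real systems can decouple the two. Recovery of
planted drivers here demonstrates that the *pipeline* ranks true drivers
first when drivers exist; it cannot certify causal claims on field data.

## Numerical and testing choices

- Seeds: every stochastic stage derives 32-bit substreams from a master
  seed and stage/sample labels, so stages are independently reproducible
  and insensitive to execution order; library code saves and restores the
  caller's RNG state.
- Problem sizes in the test suite are deliberately modest — 24–60-sample
  simulations, 50–1000 rarefaction iterations, 60–10⁴ null iterations,
  100–500 trees, 200 null replicates for calibration checks — sized so
  the full suite runs in a few minutes on one CPU while every tolerance
  is still derived from binomial or hypergeometric error, not from slack.
- Degenerate inputs fail loudly and specifically: all-zero abundance
  vectors, zero-total samples, confounded PERMANOVA factors, constant
  responses, zero-variance functions each have a named error; empty taxa
  and below-depth samples are retained/excluded with reports instead.

## Known limitations

Presence/absence Raup–Crick, phylogenetic null models (βNTI), NMDS,
constrained ordination, coverage-based richness standardization,
negative-binomial differential abundance (the responder screen here is a
deliberate fold-change + rank-test substitute), and restricted permutation
designs are out of scope. The RC null pool treats samples as exchangeable
contributors of occurrence weights; with very unbalanced designs a
grouped pool (supported via the `pool` argument) is advisable.
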