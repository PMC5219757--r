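---
title: "Discovering regulatory modules from TF co-binding data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering regulatory modules from TF co-binding data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's own account of the method: the model and
its assumptions, the tunable parameters and why their defaults are what
they are, what the synthetic generator emulates (and does not), the
numerical choices, and the known limitations.

## 1. From summit calls to documents

The raw input is one table of point calls per factor: `(chrom, summit)`
pairs, the output dialect of summit-resolution ChIP-seq event callers,
optionally carrying a motif-match flag and a cell-type label.  Calls
whose summit falls inside a blacklist interval (half-open BED) are
removed first.

Each summit is expanded to the half-open interval
`[summit − expand_bp, summit + expand_bp)` and overlapping intervals are
merged transitively per chromosome (`GenomicRanges::reduce` with
`min.gapwidth = 0`, so intervals that merely touch stay separate — two
summits merge exactly when they are closer than `2 × expand_bp`).  Merged
spans holding fewer than `min_sites` calls are discarded.  The retained
spans are the *co-binding regions*; the matrix of per-region, per-factor
site counts is the corpus.

* `expand_bp = 50` — ChIP-seq summit resolution is roughly 30–50 bp, and
  a conservative merge distance avoids welding adjacent regulatory
  elements together, which would inflate apparent multi-module usage.
  100 bp gives similar module structure.
* `min_sites = 3` — a "co-binding" region needs at least three sites;
  2 or 4 behave similarly.  The same threshold reappears in the module
  usage rule.

Coordinates are 0-based half-open everywhere internally; BED output is
emitted as-is.  Expansion clips at 0; there is no chromosome-length clip
because no genome file is assumed.  Duplicate calls (same factor, same
summit) stay distinct sites — the corpus counts sites, not unique
positions.

## 2. The topic model

Regions are documents, binding sites are words over the factor
vocabulary, modules are topics.  A hierarchical Dirichlet process prior
lets the number of modules K grow with the data instead of being fixed.

Inference is direct-assignment collapsed Gibbs sampling: each token's
topic is resampled from

\[
p(z = k) \propto (n_{jk} + \alpha_0 \beta_k)\,
\frac{n_{kw} + \eta}{n_k + V\eta},
\qquad
p(z = \text{new}) \propto \alpha_0 \beta_u / V .
\]

Once per sweep the global stick weights β are resampled from simulated
table counts, and both concentrations are resampled under vague
Gamma(1, 1) priors (α₀ by the standard auxiliary-variable scheme, γ by
the Escobar–West update).  Topics that end a sweep empty are pruned and
their stick mass returns to the unallocated remainder.

* `eta = 0.1` — the symmetric Dirichlet on module-over-factor
  distributions.  Small η encodes the prior belief that a module involves
  only a few factors; 0.01–1 give similar structure.
* `max_iter = 2000` — the chain runs a fixed number of sweeps with no
  early stopping; mixing is typically reached by about half that.
* Runs are exactly reproducible given the seed: all randomness flows
  through R's RNG.

Two sampler choices were made after measuring mixing failures, and they
matter:

1. **Random-scan schedule.** With a systematic document-order scan, the
   topics for structure appearing early in the corpus nucleate first,
   the document-level concentration then adapts downward, and structure
   late in the corpus is persistently under-split (in direct/indirect
   experiments the first factors' contexts separated and the last ones
   never did).  A fresh token permutation every sweep removes the
   asymmetry.
2. **Multistart over diverse initializations.** A chain started from one
   topic finds compact solutions but almost never *splits* a topic that
   wrongly fuses two disjoint word sets; a chain started from 20
   dispersed seed topics finds fine splits but almost never *merges*
   duplicate topics.  Single-token Gibbs moves cross between these modes
   only on impractical timescales.  `fit_hdp_multistart()` therefore
   pairs every seed with both starts (default 3 seeds × {1, 20} = 6
   chains) and keeps the run with the highest final joint collapsed
   log-likelihood \(\log p(w \mid z, \eta) + \log p(z \mid \beta,
   \alpha_0)\).  Measured on planted data, this statistic selects the
   compact mode when the truth is compact and the split mode when the
   truth is split.  A word-only likelihood was tried and rejected: it
   increases monotonically with K and always prefers fragmented
   solutions.

The selection statistic is a documented interpretation of "highest data
likelihood"; held-out likelihood would also be defensible but is not
used.

After fitting, empty topics are dropped and modules are relabeled
densely by descending site count.  The assignment table records the
module of every site; its token order within a region is the
deterministic factor-sorted order of the bag-of-words corpus, not
genomic position.

## 3. The interpretive layers

All z-scores use the sample standard deviation (n − 1); constant vectors
map to zero, so they can never pass a cutoff — this guards the
divide-by-zero case and errs on the side of making no call.

* **Participation** — column z-score (a factor's profile across modules)
  > 1.
* **Main drivers** — row z-score (a module's profile across factors)
  > 1, ranked by z (ties broken by factor name), concatenated into the
  module label (capped at 8 names).  Note a numerically dominant second
  factor can still fail the z > 1 rule when one factor holds most of the
  row's mass; the calls follow the rule, not intuition.
* **Module usage** — a region uses a module when ≥ `min_sites` of its
  sites are assigned to it *and* the count's z-score standardized within
  the region across all K modules exceeds 1.  The axis of that z-score
  is genuinely ambiguous in prose; `usage_z_axis = "region"` is the
  default and `"module"` (standardize each module column across regions)
  is available.  At small K the within-region rule is strict: with only
  two non-zero entries `(a, b)` over K = 6 columns, `z_b > 1` requires
  a near-tie `|a − b| ≲ 1`.  At the scale the rule was designed for
  (K ≈ 50, most entries zero) it is permissive.  This is why desk-scale
  multi-module detection rates are far below what the same rule yields
  on large compendia — a property of the rule, not of the fit.
* **Module groups** — average-linkage clustering on 1 − Pearson(module
  rows), tree cut at 0.5; constant rows are treated as uncorrelated.
* **PCA** — performed over the module dimension: factors are
  observations, module columns are mean-centered, no scaling.  Loadings
  live over modules and are orthonormal; variance fractions sum to 1.
  (The alternative orientation — modules as observations — contradicts
  the requirement that loadings be over modules, so it was not used.)

## 4. Baselines and the fidelity metric

k-means (Euclidean, seeded k-means++ with 10 restarts, Lloyd iterations)
and NMF (Frobenius loss, multiplicative updates, 500 iterations, seeded
uniform initialization) produce k × V module matrices at a fixed k for
comparison.  The *fidelity* of any decomposition is the Pearson
correlation between the upper triangles of two TF–TF correlation
matrices: one computed over regions from the original matrix, one over
modules from the k × V matrix.  Zero-variance factor columns are dropped
with a warning.  Fidelity is scale-free in the module rows, equals 1
exactly when the "decomposition" is the original matrix, and is compared
at equal k between methods.  Raw counts are used (not log counts).

## 5. Direct and indirect binding

Sequence-specific factors are split into `dX` (motif present) and `iX`
(motif absent) pseudo-factors; splitting conserves site counts and
expands the vocabulary.  The *diversification score* of X is
`1 − Pearson(Φ[, dX], Φ[, iX])` — 0 when direct and indirect binding
share co-binding context, up to 2 when anti-correlated.

The random forest predicts a region's X-binding mode from the other
factors' counts only: rows containing `dX` xor `iX` sites (mixed regions
are excluded and counted — the conservative reading), every other split
pair's d/i columns summed so that co-binding *identity*, not motif
status, is the feature, and X's own columns removed.  Five forests (500
trees, √p features per node, from-scratch Rcpp implementation since no
forest package is available in the environment) are fitted on distinct
seeded stratified 80% subsets; the mean held-out accuracy is reported
(balanced accuracy as a secondary column).  Label-shuffle experiments
hold at chance, confirming no leakage through the feature construction.

## 6. External-evidence checks

* **PPI rediscovery** — an interaction is rediscovered if both partners
  are main drivers of one module.  The permutation test fixes baits,
  redraws each partner uniformly from the vocabulary (self-pairs
  disallowed, duplicate pairs collapsed), and reports the +1-corrected
  Monte-Carlo p-value — never 0, in (0, 1].  200 permutations resolve p
  to about the 0.05 level.  Because the rediscovery count is a small
  integer with heavy ties, the p-value is conservative: under a null PPI
  set the fraction of p < 0.05 sits near the low edge of its tolerance.
* **Annotation overlap** — a region is annotated if it overlaps a track
  interval by ≥ 1 bp (half-open on both sides); per module, the fraction
  is over the regions using it.
* **Cross-cell-type analysis** — regions are built independently per
  cell type (never merged across types), documents are concatenated with
  origin tags, and per-module cell-type fractions are computed over the
  regions using each module.
* **Spacing** — signed distance from each anchor-factor site to the
  nearest partner site within a window; a histogram mode reveals spacing
  constraints.

## 7. The synthetic world

The generator emits the statistical structure the analysis assumes — and
only that:

* K = 6 planted modules over V = 30 factors, each a symmetric
  Dirichlet(0.05) draw truncated to its top 8 factors and renormalized:
  sparse, interpretable module distributions.
* 3000 regions; 20% use two modules with equal weights, the rest one.
* Sites per region: 3 + Poisson(5), so the min-3 filter never removes a
  planted region.
* Geometry: anchors every 1000 bp on one synthetic chromosome, site
  jitter uniform ±40 bp.  Two structural guarantees are enforced at
  config time: `anchor_spacing > 2(expand_bp + jitter)` (planted regions
  never merge) and `jitter < expand_bp` (a planted region never splits),
  so region construction round-trips the planted regions exactly and
  recovery can be scored by position.  A ±100 bp jitter was considered
  — it is closer to raw data but breaks the round-trip guarantee that
  all recovery scoring rests on.
* Optional layers: per-cell-type module-usage biases, module-conditional
  annotation tracks, and a separate direct/indirect world in which each
  split factor's direct and indirect sites co-occur with partner pools
  whose overlap is controlled by a divergence knob in [0, 1] (0 =
  identical pools, 1 = disjoint by construction).

What a green recovery test establishes: the sampler, bookkeeping, and
matching are correct on data drawn from the model the method assumes.
What it does not establish: performance on real compendia, where regions
are not equally sized or spaced, factor distributions are not Dirichlet,
binding strength and mappability vary, replicate structure exists, and
K is an order of magnitude larger.  Scale claims from the reference
setting (e.g. specific module counts or fidelity values) are not
reproducible at desk scale and are not asserted anywhere in the tests.

## 8. Numerical choices and degenerate inputs

* Recovery scoring aligns inferred and planted modules by Hungarian
  assignment (`clue::solve_LSAP`) on cosine similarity, padded to
  square; token accuracy is counted at (region, factor) granularity as
  the multiset overlap between planted and mapped assignments.
* A corpus whose documents all repeat a single word collapses to one
  topic only under a small *fixed* top-level concentration (the unit
  test fixes γ = 0.1); under the default resampled vague prior,
  interchangeable topics legitimately retain posterior mass.
* Empty matrices, all-zero corpus rows, fewer distinct rows than k,
  negative NMF input, missing motif flags, and unknown factor labels all
  raise early, named errors; all-zero rows are excluded from the corpus
  with a warning (they cannot occur after the min-sites filter).
* The pipeline aborts with the failing stage's name and verifies that
  every declared output file exists and is non-empty before writing its
  manifest.

## 9. Known limitations

* No split–merge MCMC moves: mode-crossing is delegated to the
  multistart, which is effective but approximate; K can vary by ±1–2
  across seeds on hard corpora.
* The usage rule's small-K strictness (section 3) makes multi-module
  census rates at K ≈ 6 incomparable to large-K settings.
* The random forest is a minimal CART implementation: adequate for count
  features at these sizes, but without probability calibration,
  variable importance, or missing-value handling.
* Strand is ignored throughout (point calls are strandless), and motif
  determination is upstream — the package consumes a boolean flag.
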