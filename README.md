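# tfmodules

Discovery of combinable regulatory modules from multi-factor in vivo
binding data.

## The problem

ChIP-seq compendia profile the genome-wide binding of dozens to hundreds
of *trans*-acting factors (TFs) in one cell type.  Factors bind in dense
clusters, and the clusters are not arbitrary: recurring *regulatory
modules* — sets of factors that bind together, such as CTCF + cohesin,
the Pol2/promoter machinery, or AP-1 — combine to build each regulatory
region.  Hard clustering (k-means, SOM) forces every region into a single
cluster and therefore needs thousands of clusters to describe data in
which many regions mix two or more modules.

`tfmodules` treats the problem as topic modeling.  Pooled summit calls
are merged into *co-binding regions*; each region is a "document" whose
"words" are TF binding sites; a hierarchical Dirichlet process (HDP)
topic model learns

* a **module-TF matrix** `Φ` (K modules × V factors: sites contributed by
  each factor to each module), with K inferred from the data, and
* an **assignment table** mapping every binding site to one module,

summarized further into a region-module matrix, z-score participation
("factor f participates in module k if the column z-score exceeds 1") and
main-driver calls (row z-score > 1), per-region module-usage calls
(≥ 3 sites assigned and within-region z > 1), module groups
(average-linkage clustering at Pearson-distance 0.5), and PCA over the
module dimension.

The model is fitted by direct-assignment collapsed Gibbs sampling with a
random-scan schedule; the document- and top-level DP concentrations are
resampled under vague Gamma(1, 1) priors, and a multistart (seeds ×
compact/dispersed initializations) keeps the run with the highest joint
collapsed log-likelihood.

Also included: k-means and NMF baselines with a TF-TF correlation
*fidelity* metric and module matching; direct/indirect binding analysis
(dX/iX splitting by motif presence, diversification scores, a random
forest that predicts direct vs indirect binding from co-binding partners
alone); protein-interaction rediscovery with a permutation test;
epigenomic annotation overlap; cross-cell-type module analysis; and a
seeded synthetic-data generator with planted ground truth that makes the
whole pipeline testable without downloads.

## Worked example

```r
library(tfmodules)

cfg <- synthetic_config(n_factors = 12, n_modules = 3, n_regions = 400,
                        seed = 42)
ds <- simulate_binding_data(cfg)
regions <- build_cobinding_regions(ds$calls, expand_bp = 50, min_sites = 3)
m <- build_region_tf_matrix(regions, colnames(ds$truth$phi))
corpus <- corpus_from_matrix(m)
fit <- fit_hdp_multistart(corpus, seeds = c(1, 2, 3), eta = 0.1,
                          max_iter = 1000)
out <- extract_outputs(fit, corpus)
call_main_drivers(out$module_tf)
sc <- score_recovery(ds$truth, out$module_tf, out$assignments)
cat(sprintf("recovery: K = %d (planted %d), matched cosine %.3f, token accuracy %.3f\n",
            sc$k_inferred, sc$k_true, sc$mean_cosine, sc$token_accuracy))
```

prints

```
co-binding regions: 400 regions, 3197 sites ( 0 sites dropped by min_sites filter)
HDP state: K = 3 modules, 3197 tokens, final log-likelihood -2913.715 (seed 2)
M01: TF02
M02: TF03
M03: TF05+TF08
recovery: K = 3 (planted 3), matched cosine 1.000, token accuracy 0.994
```

i.e. the sampler recovers exactly the three planted modules (cosine 1.0
after Hungarian matching) and reassigns 99.4% of the sites to the right
module.  Module labels are the main drivers ranked by z-score.  Module
usage and the multi-module census follow from the assignments:

```r
rmm <- region_module_matrix(out$assignments, nrow(out$module_tf))
usage <- call_module_usage(rmm, min_sites = 3, z_cut = 1)
multi_module_census(usage)
#>   0   1
#>  51 349
```

349 of 400 regions are called as using one module (this world planted no
multi-module regions; see the vignette for why the usage rule is strict
at small K).

## Command line

A subcommand CLI is installed with the package:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/tfmod", package = "tfmodules"))')
Rscript $CLI simulate      --out demo --seed 3 --regions 300
Rscript $CLI build-regions --calls-dir demo/calls --out demo/k562
Rscript $CLI fit           --matrix demo/k562_region_tf_matrix.tsv \
                           --out demo/fit --seeds 1,2,3
Rscript $CLI run           --calls-dir demo/calls --out demo/full
```

## Layout

* `R/`, `src/` — implementation (regions, HDP sampler, analysis layers,
  baselines, direct/indirect, evaluation, synthetic generator, pipeline).
* `vignettes/discovering-regulatory-modules.Rmd` — the methods vignette:
  model, assumptions, parameter choices, what the synthetic world does
  and does not establish, known limitations.
* `tests/testthat/` — unit, property, and acceptance tests.
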