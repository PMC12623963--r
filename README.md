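# foldrank

Model ranking, scoring and evaluation for protein tertiary-structure
prediction pipelines.

Modern structure predictors generate thousands of candidate models per
target, and for hard targets — shallow alignments, multi-domain
architectures, alternative conformations — the hardest step is not
generating a good model but *finding* it in the pool and judging it
afterwards. `foldrank` implements, in one tested R package, the
computations that surround the neural predictors in such a pipeline:

* **MSA engineering** — per-column alignment depth profiling,
  template-hit-based domain segmentation with disorder-aware boundary
  refinement, pairing of per-domain alignments by shared sequence
  identifiers, gap padding, and profile-based alignment augmentation
  (A3M/FASTA in and out).
* **Structure comparison** — Kabsch superposition and deterministic
  seed-and-refine TM-score and GDT-TS on CA traces, with a compiled
  (RcppArmadillo) core fast enough for pool-scale pairwise matrices.
  TM-score is normalized by the reference length
  (d0 = max(0.5, 1.24·(L−15)^⅓ − 1.8)); GDT-TS averages the maximal
  superimposable fractions at 1/2/4/8 Å.
* **Consensus ranking** — the pairwise similarity score (PSS = a model's
  mean TM-score to the rest of the pool), min-max score aggregation,
  K-means model clustering, greedy structural-diversity filtering, and
  the five CASP16 MULTICOM-style selection strategies (`multicom_ai`,
  `multicom_gate`, `multicom_llm`, `multicom`, `multicom_human`).
* **Fragment assembly** — divide-and-conquer stitching of overlapping
  region models by superposition over shared residues, with per-junction
  RMSD reporting.
* **Evaluation** — the CASP-style Z-score protocol (standardize per
  domain, exclude Z < −2 outliers, re-standardize, accumulate positive
  Z, average alternative-conformation domain pairs), TM-score threshold
  summaries, head-to-head comparisons and the one-sided paired Wilcoxon
  signed-rank test.
* **Synthetic fixtures** — seed-pure generators for reference CA chains,
  noise-controlled decoy pools with planted conformational clusters and
  calibrated confidence scores, depth-controlled MSAs and template-hit
  tables, so everything above runs with no external data.

See `vignettes/foldrank-methods.Rmd` for the models, parameters and
design decisions.

## Worked example: rescuing a minority conformation

A classic failure mode of consensus ranking: 90% of a pool is a wrong
conformation (here, a helix hinged 70° at its midpoint), the correct
fold sits in a 10% minority, and every similarity-driven score prefers
the crowd. Clustering first, then taking the best-scored representative
per cluster, guarantees the minority is represented:

```r
library(foldrank)

ref  <- make_reference_chain(48, "helix", rng_seed = 7)
spec <- decoy_pool_spec(
  n_models = 100, sigma_grid = 1,
  conformations = list(
    list(weight = 0.9, hinge_angle = 70, generator = "af2"),
    list(weight = 0.1, hinge_angle = 0,  generator = "af3")),
  plddt_rho = 0.5, rng_seed = 7)
pool <- make_decoys(ref, spec, truth_scores = "tm")

sim    <- pairwise_matrix(pool$models, "tm")
scores <- score_table(data.frame(model_id     = pool$truth$model_id,
                                 plddt_global = pool$truth$plddt,
                                 gate         = pool$truth$plddt / 100))
sel <- select_top(pool$models, sim, scores,
                  selection_config("multicom_gate", rng_seed = 7))
sel$true_tm <- pool$truth$true_tm[match(sel$model_id, pool$truth$model_id)]
print(sel, digits = 3)
#>   rank  model_id   criterion score true_tm
#> 1    1 decoy_024 gate+kmeans 0.961   0.702
#> 2    2 decoy_085 gate+kmeans 0.918   0.378
#> 3    3 decoy_096 gate+kmeans 0.879   0.424
#> 4    4 decoy_030 gate+kmeans 0.869   0.402
#> 5    5 decoy_046 gate+kmeans 0.722   0.394
```

The selection includes `decoy_024` — a minority-cluster model whose true
TM-score (0.702, the best in this pool) is far above the wrong
conformation's ~0.4. Pure consensus ranking picks from the majority:

```r
p <- pss(sim)
names(p)[which.max(p)]   # "decoy_037", true TM 0.454
```

A true TM-score above 0.5 means the fold is right; above 0.9 is
near-native. Here clustering turned a would-be failure (top-1 from the
wrong conformation) into a correct-fold submission.

## Command line

A thin wrapper over the same functions is installed at
`inst/cli/foldrank`:

```sh
foldrank tmscore ref.pdb model.pdb        # prints e.g. 0.8731
foldrank simulate decoys --out pool/ --seed 3 --n 50 --length 60
foldrank rank --strategy multicom_gate --models pool/ \
         --scores pool/scores.tsv --out selection.tsv --seed 3
foldrank evaluate --gdt gdt_table.tsv --pairs alt_pairs.tsv
foldrank assemble frag1.pdb:1-60 frag2.pdb:41-100 --out full.pdb
```

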