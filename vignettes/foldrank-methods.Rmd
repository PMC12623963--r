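---
title: "foldrank: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{foldrank: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(foldrank)
```

## What this package computes

`foldrank` implements the non-neural computations that surround deep
learning predictors in an integrative protein tertiary-structure
prediction pipeline: engineering the multiple sequence alignments (MSAs)
that feed the predictors, scoring predicted models against a reference
(TM-score, GDT-TS), ranking and selecting models from large decoy pools
when no native structure is available, stitching overlapping fragment
models, and standardizing per-domain accuracies across predictors for
benchmark-style evaluation. Every stage is exercisable on synthetic
fixtures generated in code, so the whole pipeline runs with no external
data or network access.

## Structure comparison

### Superposition

`kabsch_superpose()` computes the least-squares rigid transform mapping a
mobile CA set onto a reference (SVD-based, reflection-corrected so the
rotation is proper). The compiled seed-and-refine search used by the
scores employs an equivalent quaternion (Horn) fit with a 4×4 Jacobi
eigensolver, chosen because pool-scale pairwise matrices call it tens of
thousands of times per target.

### TM-score and GDT-TS

Residue correspondence is established by shared residue numbers; the
TM-score is normalized by the reference length $L$:

$$\mathrm{TM} = \max_{\text{superpositions}} \frac{1}{L}
  \sum_i \frac{1}{1 + (d_i/d_0)^2}, \qquad
  d_0 = \max\!\big(0.5,\; 1.24\,(L-15)^{1/3} - 1.8\big)$$

GDT-TS is the mean over the 1/2/4/8 Å cutoffs of the maximal fraction of
reference residues superimposable within the cutoff. Both scores are
maxima over rigid superpositions, which no algorithm can enumerate; the
search is the standard deterministic heuristic: superpose on a seed
window, then iterate "keep residues within the cutoff, re-superpose"
until the selected set is stable. Seed window lengths default to
$\{3, 5, 7, L/2, L\}$ (`scoring_params()`), placed as a non-overlapping
tiling along the chain. Chains of at most 30 matched residues instead get
an exhaustive sweep (all window lengths and positions) plus refinement
from a 15° rotation grid: at that size the per-residue granularity of
GDT-TS is large, so the search must land on the exact optimal subset, and
the extra work is negligible. There are no randomized restarts — scores
are bit-reproducible.

Because every superposition visited yields an achievable value of these
max-type scores, a brute-force scan (dense rotation grid plus every
contiguous seed) provides a lower bound that a correct implementation
must reach; the test suite asserts exactly that on small random chains,
and the implementation routinely exceeds the one-shot scan because its
refinement iterations tighten the bound.

Two design choices deserve emphasis. First, TM normalization is by the
first argument (the reference); `pairwise_matrix()` symmetrizes by
averaging the two directions. For pools sharing one residue set the two
directions coincide exactly (equal normalization length and symmetric
distances), and the matrix is computed one-sided in compiled code.
Second, scoring is CA-only: the evaluation conventions this package
follows are backbone-centric, and side-chain metrics are out of scope.

## MSA engineering

`column_depth()` counts non-gap rows per match column (query included);
`depth_window()` gives interval means. Shallow terminal windows are a
practical diagnostic for regions a predictor is likely to get wrong.

`filter_hits()` applies the template significance filter: keep hits with
e-value ≤ 1, aligned target length strictly greater than 40 residues and
coverage strictly greater than 0.5. The coverage field is taken as
supplied by the hit-table producer (aligned length over template length
in the synthetic generator); the filter itself does not recompute it.

`segment_domains()` turns surviving hits into a partition of the target:
maximal continuous aligned regions become domains; unaligned gaps longer
than 40 residues become domains of their own; shorter internal gaps are
split at their midpoint between flanking domains (this preserves full
coverage without inventing sub-domains), and short leading/trailing gaps
are absorbed into the first/last domain. When a disorder track is given,
a boundary strictly inside a disordered run of at least 5 residues
(configurable) is moved to the run midpoint — a concrete, deterministic
refinement rule for the general idea that domain boundaries should not
sit inside ordered structure.

Per-domain alignments are recombined into full-length alignments three
ways (`build_domain_msa()`): rows of the full-length MSA; rows paired
across all domains by shared sequence identifier (first occurrence per
identifier per MSA, ties never re-scored — determinism over cleverness);
and residual unpaired rows embedded by gap padding (`pad_unpaired()`).
Exact duplicates by (identifier, residue string) are dropped; near
duplicates are kept, since depth is the point of the exercise.

`augment_with_profile()` appends synthetic sequences built by
substituting, at each column, the most frequent non-query residues when
their frequency among aligned residues exceeds 0.3. This is an explicit,
documented stand-in for masked-language-model augmentation: the
replacement predictor is pluggable (`profile_fn`), and the default column
profile reproduces only the frequency-driven part of what a learned
model would do.

## Consensus ranking and the five selection strategies

`pss()` is the average pairwise similarity score: a model's mean TM-score
to all other pool members. It is a strong consensus signal when good
models dominate and a systematically misleading one when a wrong
conformation dominates — the failure mode the selection strategies hedge
against.

`aggregate_scores()` min-max normalizes each score column over the models
where it is present before averaging. Raw averaging of unlike scales
(plDDT on 0–100 against scores on 0–1) would let one column dominate, so
normalization is the default, with `normalize = FALSE` available for raw
averaging. A constant column maps to 0.5 everywhere; models missing all
named scores rank last rather than erroring, so partially scored pools
remain usable. All ties break lexicographically by model id.

`cluster_models()` runs K-means on the rows of the dissimilarity matrix
$1 - S$ with $k = 5$ by default — the submission count, since the point
of clustering here is one representative per submitted slot — with a
fixed seed and 10 restarts. The feature representation (similarity-matrix
rows rather than coordinates) is a package choice: it is
length-independent and reuses the matrix the pipeline already computes.

`select_top()` dispatches the five CASP16-style strategies:

| strategy | top-1 | remaining slots |
|---|---|---|
| `multicom_ai` | global plDDT | greedy diversity filter (pairwise TM < 0.8), AF3 guarantee |
| `multicom_gate` | — | top-GATE model of each K-means cluster, AF3 guarantee |
| `multicom_llm` | AF3 ranking score | mean of GATE and plDDT |
| `multicom` | mean of AF3 ranking and GATE | mean(GATE, plDDT), GATE, GCPNet-EMA, EnQA, PSS in turn |
| `multicom_human` | mean of GATE and plDDT | global plDDT |

For `multicom`, each criterion in turn contributes its best not-yet-used
model, which resolves duplicate picks deterministically. For
`multicom_human`, slots 2–5 follow global plDDT, reflecting that its
ranking ultimately leaned on plDDT once the top-1 rule was fixed. Manual
adjustment steps are modelled as an explicit `override` list applied
last — never as heuristics.

## Fragment assembly

`assemble()` stitches overlapping region models: the first fragment is
fixed and each next fragment is Kabsch-superposed onto the growing
assembly over their shared residues. Overlap coordinates come from the
earlier fragment by default — deterministic and free of chimeric
geometry — with midpoint blending available (`overlap = "blend"`). The
per-junction overlap RMSD after fitting is reported so a user can see
when two fragments disagree about their shared region. The default
minimum overlap of 20 residues is a robustness choice: three residues
suffice mathematically, but junction stability degrades quickly below a
few turns of secondary structure.

## The Z-score evaluation protocol

`domain_zscores()` standardizes one domain's per-predictor accuracies in
two passes: standardize against the mean and standard deviation of all
present scores, drop entries below −2, then re-standardize **all**
present entries against the survivors' mean and standard deviation
(dropped entries receive a pass-2 value too; they are simply far below
it). Population standard deviation is the default with a `sample` option;
a zero deviation yields all-zero Z.

`cumulative_zscore()` averages the raw Z of each configured
alternative-conformation domain pair into one unit **before** clipping —
averaging first and clipping once reads most naturally as "include the
averaged Z into the sum", and a clip-then-average sensitivity mode is one
configuration flag away. Each predictor then accumulates the positive
part of each unit's Z, with missing submissions contributing zero. The
alternative-pair list is always explicit input, never inferred.

One property of this protocol is worth knowing: it is **not strictly
monotone**. Raising a predictor's own score can widen the pass-1 spread
just enough that a borderline outlier escapes the −2 exclusion, enlarging
the re-standardization pool and slightly *lowering* the raiser's
recalculated Z (a worked counterexample is frozen in the test suite). The
discontinuity is intrinsic to threshold-based outlier exclusion, not an
implementation artifact; away from exclusion-set changes the protocol is
monotone, and the suite asserts that.

`paired_onesided_test()` computes the one-sided paired Wilcoxon
signed-rank p-value, with the exact distribution (convolution over sign
patterns, midranks doubled to stay integral under ties) for up to 25
non-zero differences and the tie-corrected normal approximation beyond.

## Synthetic study conditions

The generators emulate the data regimes the methods are designed for,
and their defaults are fixed once:

* `make_reference_chain()` builds CA traces with 3.8 Å consecutive
  spacing — an ideal α-helix, or a self-avoiding random walk (minimum
  non-consecutive CA distance 4 Å) for globular-ish folds.
* `make_decoys()` perturbs the reference with per-model Gaussian
  coordinate noise from a σ grid, samples alternative conformations by
  weight (a hinge at the chain midpoint by a configurable angle — a
  simple, controllable way to plant well-separated clusters), and hides
  everything in random rigid frames. The truth table carries true
  TM/GDT-TS and a simulated global plDDT mixed to a target correlation ρ
  with true quality then mapped onto a 30–95 band — confidence that is
  informative but fallible, as self-estimates are.
* The two-conformation selection experiments use chains of 48 residues,
  pools of 200 models, σ = 1 Å, a 70° hinge for the dominant wrong
  conformation at 90/10 weights, ρ = 0.5, and 100 replicates; at these
  settings the planted partition is cleanly recoverable by clustering
  while confidence and consensus scores remain realistically noisy.
* `make_msa()` samples alignment rows with a per-column coverage
  profile and substitution rate, so depth pathologies (a thinly covered
  terminus) are reproducible on demand.
* `make_hit_table()` emits one significant hit per planted domain,
  shrunk by a 10-residue margin at internal boundaries so the short-gap
  midpoint rule reconstructs the planted boundary exactly at zero
  jitter, plus decoy hits that each fail one filter.

What these fixtures do **not** emulate: real protein geometry beyond CA
traces, correlated (domain-level) prediction errors, sequence-dependent
conservation structure in MSAs, or score distributions of real QA
networks. Passing tests therefore demonstrate that the algorithms
implement their definitions and reproduce the targeted failure/rescue
mechanisms — not that any particular accuracy level transfers to real
CASP targets.

## Numerical and degenerate-input conventions

* Scores are deterministic; the only RNG in the package is in the
  synthetic generators and K-means, both seed-controlled.
* Superposition of degenerate (e.g. collinear) seeds is handled by the
  eigen-solver without special-casing; refinement immediately reselects.
* `domain_zscores()` with fewer than two present scores warns and
  returns all-absent; all-equal scores give all-zero Z.
* Score tables keep missing cells absent (`NA`), never zero.
* PDB insertion codes are rejected loudly rather than renumbered;
  altlocs resolve by highest occupancy, then first seen.
* AlphaFold3-style mmCIF output must be converted to PDB by the user
  before reading; the package reads PDB chains only.

## Known limitations

* TM-score/GDT-TS values can deviate slightly from other published
  implementations (different seed schedules and refinement caps); the
  suite bounds them against a brute-force scan instead of a particular
  binary.
* Residue correspondence requires shared numbering; alignment-based
  correspondence between different sequences is out of scope.
* The evaluation module consumes accuracy tables; it does not manage
  model archives or compute interface scores.
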