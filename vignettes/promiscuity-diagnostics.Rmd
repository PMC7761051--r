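---
title: "Diagnostic machine learning for compound promiscuity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Diagnostic machine learning for compound promiscuity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The model and its assumptions

`promdiag` asks whether chemical structure separates promiscuous
(multi-target, MT) from non-promiscuous (single-target, ST) screening
compounds, and whether that separation is carried by nearest-neighbor
(analog) relationships. The analysis is *diagnostic*: models are not
tuned for deployment; their accuracy under controlled dataset
modifications is the measurement.

The data model is a ternary activity matrix over compounds and targets:
every pair is ACTIVE, INACTIVE, or absent (untested). Two per-compound
statistics drive everything downstream:

* promiscuity degree `PD(c)` — number of targets with an ACTIVE outcome;
* test frequency `TF(c)` — number of targets with any recorded outcome.

Keeping explicit negatives matters: an MT-/ST-CPD group is only valid
when every member was *tested* on every group target, so an ST-CPD's
PD = 1 is evidence of specificity rather than of sparse testing. This
"data completeness" contract is enforced by `verify_completeness()` and
is the reason UNTESTED never qualifies as inactive during candidate
selection.

Assumptions inherited from the screening setting: outcomes are binary
(no potencies); interference-prone compounds (PAINS, aggregators,
chemical liabilities, FLuc inhibitors, cytotoxics) are removed up front
so that ACTIVE annotations are trustworthy; assays with hit rates above
`max_hit_rate` (default 2%) are dropped as likely confirmatory or
artifact-prone screens. Interference flags are *inputs*: recomputing
substructure catalogs is upstream tooling's job, and the pipeline's
contract is flag-based.

## Group sampling

For each MT-CPD (PD at or above the threshold, 5 by default, 3 as the
sensitivity setting) and each of its targets, the eligible ST candidates
are the PD-1 compounds active on that target and explicitly inactive on
every other group target; one is drawn uniformly at random. MT-CPDs with
no eligible candidate on any target are omitted. Decisions taken where
the design was genuinely open:

* **ST reuse across groups is allowed** (within a group each compound
  appears once). This maximizes the number of matched ST-CPDs; at the
  intended data scale reuse is rare, and the generator was explicitly
  designed so that it stays rare (see below) because duplicated
  instances leak information across pair-level CV splits.
* **Iteration order is sorted by MT identifier** and each MT-CPD's draw
  uses a sub-seed derived from its identifier, so results do not depend
  on input file ordering.

## Similarity, conditions

Compound comparison is Tanimoto similarity over 2048-bit Morgan
radius-2 fingerprints (RDKit backend, or precomputed bit strings so the
whole ML path runs without a chemistry toolkit). Conventions: the 0/0
case (two empty fingerprints) scores 0, which can only deflate NN
statistics; distance is `1 - Tc` throughout. A MACCS provider slot
exists as a control representation but is untested by default.

The three experimental conditions are FULL; RANDOM_REMOVAL (drop
`floor(0.5 n)` groups uniformly — the size control); and NN_REMOVAL:
remove the 25% of groups whose MT-CPD is most similar to another group's
MT-CPD, then, among survivors, the groups whose ST-CPDs are most similar
to ST-CPDs outside the group, until the net cut is 50%. Open-design
decisions:

* group-level ST scores aggregate by **max** over the group's ST-CPDs
  (NN removal targets closest relationships; `mean` is available);
* the two passes are **sequential and disjoint**, guaranteeing the exact
  size match with the random control; ties break on MT identifier;
* scores are computed on the full dataset before ML, not per fold — the
  condition is a property of the dataset, not of a split.

## Diagnostic ML protocol

Per external trial (10 by default): draw one ST-CPD per group to balance
classes; split the MT/ST *pairs* 80/20 (both members of a pair stay on
the same side, so no compound and no matched partner leaks); run
internal trials on the training pairs to pick the hyper-parameter grid
point with the best mean internal balanced accuracy; refit on all
training pairs; evaluate on the test pairs. Grids: k-NN k in {1,3,5};
RF n_estimators {10,100,250,500} x min_samples_split {2,3,5,7,10}; SVM
C in {0.1,...,1000} with the linear and Tanimoto kernels competing
inside the grid.

Numerical and protocol decisions:

* "ranking by decreasing fingerprint distance" is read as
  **nearest-first**; the literal farthest-first reading would contradict
  the k-NN principle. Distance ties break on lexicographic compound
  identifier, making predictions invariant to training-set permutations.
* inner-loop selection uses mean internal BA; ties resolve toward the
  more parsimonious grid point (smaller k, fewer trees, smaller C,
  linear before Tanimoto kernel).
* MCC is 0 by convention when a confusion marginal is zero; BA requires
  both classes present (guaranteed by pair-level splits of a balanced
  set); F1 = 2TP/(2TP+FP+FN).
* ROC uses SVM decision-function values (not calibrated probabilities)
  and RF class-vote fractions; AUC is the rank statistic with midrank
  tie handling. k-NN scores (MT fraction among k neighbors) support an
  AUC but are not part of the default report.
* Seeds: one master seed; per-trial and per-task sub-seeds derive from
  it by a fixed integer mix, so runs are bit-reproducible and trials
  independent.
* RF and SVM *solvers* are delegated to scikit-learn via a batched
  subprocess worker (`inst/python/sklearn_worker.py`); R prepares all
  splits, the Tanimoto Gram matrices and labels, and consumes raw
  predictions. k-NN and the kernel itself are implemented in R. This is
  the only practical standard learning library in the target
  environment, and the division of labor keeps every scientific decision
  on the R side.

## The synthetic world: what it emulates, what it does not

`sim_config()` defaults are the package's stated world:

| parameter | default | rationale |
|---|---|---|
| `n_series` / `series_size` | 50 / 8 | 25 MT/ST series pairs -> 200 planted groups, the benchmark size |
| `pd_mt` | 5 | the standard MT threshold |
| `n_targets` | 240 | with TF ~ 90 a compound covers ~35% of targets, matching screening-scale coverage (compounds are tested in roughly a third of assays); group target sets are then rarely covered by chance, keeping cross-group ST reuse rare |
| `test_frequency_target` | 90 | the reported median test frequency for biochemical screening compounds |
| `core_bits_per_series` | 80–160 | series-level variation in core size makes the NN similarity distribution broad (0.3–0.8), as in real analog series, instead of a degenerate point mass |
| `substituent_bits_per_compound` | 20–60 | member-level variation |
| `promiscuity_signal` | 0.9 | benchmark regime: 90% of families planted series-coherently |
| `st_coherence` | 0.7 | ST-side analog tendency weaker than MT-side, reproducing the observed NN asymmetry |
| `background_hit_rate` | 0.002 | realistic primary-screen hit rate, well below the 2% assay cap |
| `label_noise` | 0.01 | 1% outcome flips; screening assays are noisy |

Each MT-series member becomes one group's MT-CPD with its own target
set; the paired ST series contributes `pd_mt` dedicated ST-CPDs per
group. With probability `1 - promiscuity_signal` a family's activity
pattern is planted on fresh structurally random compounds instead, so at
signal 0 structure carries no class information and diagnostic BA sits
at chance — the key negative control.

Noise is applied after planting, so it can break eligibility (a flipped
fill outcome gives an ST-CPD PD = 2) — deliberately exercising the
rejection paths. Consequently the recovered group count under the
default 1% noise is ~150–180 of the 200 planted; with noise 0 recovery
is at least 95%.

What the generator does **not** emulate: real chemistry (bits are
abstract, so substructure-level effects like PAINS alerts cannot emerge
from structures), the empirical assay-size distribution, potency
gradations, and correlated assay noise. A green benchmark therefore
establishes that the *pipeline* detects planted structure-activity
relationships of realistic shape — not that any particular biological
claim holds.

An optional SMILES-level generator (`simulate_smiles_series`) builds
scaffold + alkyl-chain series of parseable structures to exercise the
fragmentation code path with real chemistry.

## Analog detection and target networks

Full fragmentation-based analog-series extraction is replaced by a
deliberate proxy: every acyclic single bond between heavy atoms is cut
once; the larger fragment is a core key when it has at least twice the
substituent's heavy atoms (ratio configurable); compounds sharing a core
key are analogs. The proxy is validated only on libraries with known
series structure, and for fingerprint-only synthetic data analog
relationships come from generator ground truth, keeping structure
parsing off the main test path. Target networks connect targets sharing
at least 50 MT-CPDs (node weight = MT-CPD count, edge weight = shared
count); functional annotations are an optional input, never computed.

## Acceptance benchmarks and scaling

The acceptance suite runs the stated world (200 planted groups,
s = 0.9, 10 external trials, 10 generator seeds) but scales the inner
loop for a single-CPU time budget: 2 internal trials and grid subsets
(RF n_estimators {10,100} x min_samples_split {2}; SVM C {1,10,100} with
both kernels; k-NN full grid). The signal-recovery curve uses 3
generator seeds per signal level and the NN-distribution control uses a
smaller world (15 families of 6) for 20 seeds. Orderings and bands —
not absolute accuracies — are the assertions, and they are insensitive
to this scaling. Benchmark accuracies here are higher than on real
screening data (the planted signal is cleaner); only the qualitative
pattern (FULL >= random removal >= NN removal, NN drop dominating,
k-NN below the best of RF/SVM) is the reproduced result.

## Known limitations

* Assays with "inconsistent results" cannot be detected from a ternary
  matrix; callers pre-filter.
* The scikit-learn subprocess adds ~1–2 s latency per `run_double_cv`
  call; for very large grids a persistent worker would be preferable.
* `nn_removal` never lets one group qualify under both the MT and ST
  criteria (sequential disjoint passes); a joint-ranking variant could
  remove a slightly different set.
* ST reuse across groups is permitted; in worlds where eligible
  candidates are scarce this duplicates instances across CV partitions
  and inflates accuracy. The generator keeps candidate overlap low by
  construction; real-data users should check the reuse rate
  (`length(unique(st)) / length(st)`).
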