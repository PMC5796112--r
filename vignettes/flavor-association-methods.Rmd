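---
title: "Methods: from binding-site screening to five-flavor association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from binding-site screening to five-flavor association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tcmflavor)
```

`tcmflavor` connects two classifications that rarely meet in one analysis:
the *binding-site class* of a compound on the metabotropic glutamate
receptors — orthosteric (the extracellular glutamate site) versus
allosteric (the seven-transmembrane modulator site) — and the *five-flavor*
annotation (sour, bitter, sweet, pungent, salty) of the traditional
Chinese medicines those compounds come from. This vignette documents the
statistical machinery, the choices we made where the procedure was
genuinely open, and what the synthetic-data tests do and do not establish.

## Pharmacophore model selection

A pharmacophore hypothesis generator produces many candidate models, each
summarised by seven intrinsic parameters: Specificity (expected
discrimination), N_hits (training compounds mapped), Pareto rank, Energy,
Sterics (steric overlap), Hbond (pharmacophoric concordance) and Mol_qry
(query agreement). Selection proceeds in two stages.

First, `screen_model_candidates()` keeps models whose N_hits equals the
training-set size (a model should map every compound it was built from)
and whose Pareto rank is zero, i.e. no other model is at least as good on
every parameter and strictly better on one (`pareto_rank()` computes this
by direction-adjusted pairwise dominance).

Second, `sum_ranking()` assigns each surviving model a competition rank
per parameter — Energy ascending, the rest descending — and sums them. Ties
share the *minimum* rank, and the next distinct value's rank counts all
strictly better models. Competition ranking is our choice: the procedure
we follow never states its tie rule, and the minimum-rank convention is
the simplest one that keeps ranks integer and order-preserving. Two
further conventions are ours as well, both exposed as arguments:

* **Which parameters enter the sum.** The default is the five ranked
  parameters (Specificity, Energy, Sterics, Hbond, Mol_qry). N_hits is
  excluded because the pre-screen already forces it to a constant; after
  the pre-screen its rank is 1 for every candidate, so including it
  (`include_nhits = TRUE`) shifts every sum by one and never changes the
  winner.
* **Winner ties** are broken by lower Energy, then lexicographic model id,
  and flagged in the result — low model energy is the one parameter the
  selection narrative privileges.

On the bundled nine-candidate table (`mglur_model_stats()`) these rules
select model 01 with ∑Ranking 13. Note that published rank tables computed
with unstated conventions can disagree with a strict re-ranking of their
own input statistics; we always recompute ranks from the statistics and
never ingest printed rank columns.

## Feature matching

`match_pharmacophore()` decides whether a compound's abstract feature
points (positive nitrogen NP, hydrophobe HY, negative center NC, acceptor
AA, donor DA, aromatic AR) can realise a model. It searches injective
assignments of model features to same-kind compound features by
backtracking, requiring every assigned pair to satisfy

$$|d_\text{model}(i,j) - d_\text{compound}(i,j)| \le tol_i + tol_j ,$$

the standard distance-compatibility relaxation for tolerance spheres (the
sum of the two radii). Among feasible assignments the largest is kept,
ties broken by the lowest root-mean-square pairwise discrepancy. Matching
is on *internal geometry*, so it is invariant to rigid motion of either
point set and needs no superposition. The default match requirement is
all model features minus one, reflecting how partial mappings of a
four-feature model are treated as hits in practice; `min_matched = "all"`
tightens this. A model that omits tolerance radii gets 1.0 Å spheres. The
implementation is checked against exhaustive enumeration of all injective
assignments for instances up to 6 features.

## Drug-likeness and permeability

The filter cascade is deliberately simple and fully configurable:

* **Rule of five, "pass = ≥ 4 of 5".** The classic rule counts four
  criteria; to make a ≥ 4-of-5 rule meaningful we score five — MW ≤ 500 Da,
  logP ≤ 5, HBD ≤ 5, HBA ≤ 10, rotatable bonds ≤ 10 — with inclusive
  boundaries (a compound exactly at a limit satisfies the criterion).
* **Blood-brain barrier.** Commercial ADMET predictors are opaque; we use
  a Clark-type published linear surrogate,
  $\log BB = 0.152\,\log P - 0.0148\,\mathrm{TPSA} + 0.139$, passing at
  $\log BB \ge -1$. It is labelled a surrogate throughout: it captures the
  lipophilicity/polar-surface-area trade-off that dominates passive CNS
  penetration and nothing else (no efflux transport, no plasma binding).

Counts after each stage are monotone non-increasing by construction;
`filter_cascade()` records them in the order pharmacophore hits →
drug-like → BBB-permeable.

## Docking validation statistics

Docking setups are accepted on two statistics, both implemented here
without any docking engine:

* **Re-dock RMSD** (`pose_rmsd()`): the paired-atom root-mean-square
  deviation between an experimental ligand pose and its re-docked copy.
  Default is *no* superposition, because re-docked poses live in the same
  receptor frame as the crystal pose and superposing would hide genuine
  placement error; `superpose = TRUE` applies a Kabsch fit (via `bio3d`)
  for frame-mismatched inputs.
* **Affinity-rank correlation** (`spearman_rho()`): Ki ranked ascending
  (strongest binder first), total score ranked descending (best score
  first), then $\rho = 1 - 6\sum d^2 / (n(n^2-1))$ in the tie-free case.
  With ties we switch to average ranks and the product-moment correlation
  of the rank vectors, which is the standard tie-corrected estimator; a
  zero-variance rank vector is an error, not a silent `NA`. The bundled
  binder tables give ρ = 0.9286 (n = 7), 1.0 (n = 3) and 0.8167 (n = 9).
* **Score threshold**: every known binder must exceed a total score of 4,
  *strictly*. When affinities are missing the correlation is omitted with
  an explicit reason, never silently.

## Flavor and effect association

`trace_tcms()` maps surviving compounds to their source medicines and
deduplicates by `tcm_id` within a screening group — an herb with many hit
compounds still counts once. `flavor_frequency()` counts a k-flavored
medicine once toward each of its k flavors; this avoids double-weighting
prolific herbs, at the price that fractions across flavors can sum above
one. `effect_frequency()` ranks the traditional-effect vocabulary (Zhi
Tong, Jie Du, Qu Shi, Xiao Zhong, Huo Xue, Qu Feng, San Han — the
vocabulary is extensible) by count, ties broken alphabetically, keeping
the top three by default.

Frequency ranking alone cannot say whether "the orthosteric group is
mostly sweet" exceeds what the catalog base rates would produce, so
`flavor_enrichment()` adds a permutation test: the score is the group
fraction minus the background fraction of the flavor, and the p-value is
$(1 + \#\{\text{perm} \ge \text{obs}\})/(n_\text{perm}+1)$ over random
same-size draws from the catalog without replacement. This test is an
addition to the frequency analysis and is reported in separate columns so
the plain frequency reading remains available. Defaults: 10 000
permutations, seeded; results are bit-for-bit reproducible.

`build_flavor_network()` exports the tripartite target-site → flavor →
function summary as an edge list (JSON node-link and TSV), one dominant
flavor edge and three function edges per group by default.

## The synthetic generator

Real inputs for this pipeline are proprietary (commercial compound
databases, pharmacopoeia annotations), so `synthetic_spec()` defines
emulated study conditions, and all defaults are fixed once:

* 200 medicines, 500 compounds — large enough that each screening group
  traces well over 50 herbs, small enough for second-scale runs.
* Base flavor carriage probabilities (bitter 0.40, sweet 0.35, pungent
  0.30, sour 0.12, salty 0.08) shaped like a pharmacopoeia in which bitter
  and sweet dominate; every medicine carries at least one flavor.
* Planted associations: orthosteric → sweet, allosteric → bitter, each
  with enrichment delta 0.3 — a latent hit compound links to a
  flavor-carrying herb with probability base + 0.3.
* Property distributions: MW lognormal (median 350 Da), logP normal
  (2.5 ± 1.5), HBD/HBA/rotatable bonds Poisson (2, 5, 5), TPSA gamma
  (mean 80 Å²). These are documented stand-ins for a natural-product
  library, not fitted values.
* Latent hit compounds carry the site template's features jittered within
  half the tolerance spheres, which guarantees a full match by the
  triangle inequality; non-hits get uniform random features, so false
  positives occur at a realistic low rate.

Each generator draws from its own RNG stream derived from the master seed
by a stable label, so adding a generator never perturbs another's output.
`generate_binder_table(n, sum_d2)` deserves a note: it searches
deterministically for a rank permutation with *exactly* the requested
$\sum d^2$ (achievable values are the even integers up to $n(n^2-1)/3$)
and builds scores realising it, so the Spearman path can be tested against
the closed form to 1e-12 rather than against a noisy target.

What passing tests on this generator establish: the algorithms compute
their definitions exactly, the cascade bookkeeping cannot drift, and a
planted flavor-site signal of effect size 0.3 is recovered as the top
flavor with a significant permutation test in ≥ 95% of replicates. What
they do not establish: anything about real herb chemistry — the generator
has no correlated molecular properties, no realistic 3D conformers, and
flavor labels independent of chemistry except where planted.

## Numerical and reporting conventions

Reports render floats with four decimals, round-half-even. Tabular input
accepts thousands separators ("470,000") because published affinity tables
print them. Degenerate inputs fail loudly: fewer than two Ki values, zero
rank variance, mismatched atom counts, dangling herb identifiers and
unachievable $\sum d^2$ are all errors with actionable messages.

## Problem sizes

The shipped test-suite and acceptance runs use the generator defaults
(200 herbs / 500 compounds), 100 replicates for recovery properties,
199-2000 permutations for enrichment p-values inside loops (10 000 as the
single-test default), and 1000 random tables for the ranking oracle —
sizes at which every check completes in seconds while keeping Monte-Carlo
error far from the asserted margins.

## Known limitations

* The logBB surrogate and the five-criterion rule-of-five are stated
  simplifications; absolute survivor counts from proprietary screens are
  not reproducible and are never asserted.
* `match_pharmacophore()` is exponential in model features in the worst
  case; it is intended for the small (3-6 feature) models typical of
  ligand-based queries.
* The enrichment test conditions on the traced group size; it does not
  model the compound-to-herb multiplicity within a group.
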