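# tcmflavor

`tcmflavor` is an R package for an in-silico question from traditional
Chinese medicine (TCM) pharmacology: do the herbs whose compounds bind the
**orthosteric** site of metabotropic glutamate receptors (mGluRs) carry
different **five-flavor** annotations (sour, bitter, sweet, pungent, salty)
than the herbs whose compounds bind the **allosteric** site? The mGluRs are
both synaptic and umami-taste receptors, which makes the flavor taxonomy a
natural axis to test.

The package implements the full virtual-screening-to-association pipeline
as composable, pipe-friendly functions:

1. **Pharmacophore model selection.** Candidate models are described by
   seven intrinsic parameters (Specificity, N_hits, Pareto, Energy,
   Sterics, Hbond, Mol_qry). After requiring N_hits equal to the
   training-set size and Pareto rank 0, each remaining parameter is
   competition-ranked across candidates (Energy ascending — lowest is rank
   1; the others descending — largest is rank 1) and the model minimising

   ∑Ranking(m) = Σ_p rank_p(m)

   over the five ranked parameters is selected. 3D feature matching
   (`match_pharmacophore()`) then screens compound libraries against the
   chosen model by backtracking over injective same-kind feature
   assignments under the pairwise tolerance rule
   |d_model(i,j) − d_compound(i,j)| ≤ tol_i + tol_j.
2. **Drug-likeness cascade.** A rule-of-five score (pass = ≥ 4 of 5
   criteria satisfied, boundaries inclusive) followed by a linear logBB
   blood-brain-barrier surrogate, logBB = 0.152·logP − 0.0148·TPSA + 0.139,
   with pass at logBB ≥ −1.
3. **Docking validation statistics.** Paired-atom pose RMSD (optionally
   Kabsch-superposed), competition ranking, the Spearman correlation
   between ascending Ki ranks and descending docking-score ranks
   (ρ = 1 − 6Σd²/(n(n²−1)) in the tie-free case), and the strict
   "total score > 4" acceptance rule.
4. **Flavor/effect association.** Tracing surviving compounds to their
   source herbs (deduplicated per group), flavor and traditional-effect
   frequency tables, a permutation test for flavor enrichment, and export
   of the target–flavor–function tripartite network.
5. **Synthetic library generator.** Seeded generators for a TCM-like
   compound database with *plantable* site→flavor associations, binder
   tables with exact rank concordance (an analytic oracle for ρ), and pose
   pairs with exact RMSD — so the whole pipeline is testable without
   proprietary databases.

## Worked example

```r
library(tcmflavor)

# model selection on the bundled nine-candidate statistics table
sel <- sum_ranking(screen_model_candidates(mglur_model_stats(), n_training = 6))
glance(sel)
#> # A tibble: 1 × 5
#>   optimal_model min_sum_ranking n_candidates tie_broken include_nhits
#>   <chr>                   <int>        <int> <lgl>      <lgl>
#> 1 model 01                   13            9 FALSE      FALSE

# docking validation on the bundled mGluR4 known binders
validate_binders(mglur_binders("mglur4"))
#> <validation_result> 7 binders; all scores > 4.0: TRUE
#>   Ki-rank vs score correlation: 0.9286

# a complete synthetic run: simulate, screen, filter, validate, associate
m <- run_pipeline(pipeline_config(seed = 1, n_permutations = 2000), "simulate")
glance(m$results$associations$orthosteric)
#> # A tibble: 1 × 4
#>   group       n_tcms top_flavor top_effect
#>   <chr>        <int> <chr>      <chr>
#> 1 orthosteric    122 sweet      San Han
```

The model-selection sum of 13 means model 01 accumulates the lowest total
of per-parameter competition ranks among the nine candidates; the 0.9286
correlation says the docking score ranks the seven mGluR4 binders almost
exactly in order of their measured affinity; and the synthetic run
recovers `sweet` as the dominant flavor of the orthosteric group's herbs,
which is the association the generator plants.

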