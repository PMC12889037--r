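# confdiv

Sequence and conformational divergence analysis for protein homolog
families.

## The problem

Families of two-domain DNA-binding proteins — the motivating case is the
*Wolbachia* Wmk family of candidate male-killing factors, built from two
cro/CI-type helix-turn-helix (HTH) domains joined by a long inter-domain
linker (IDL) — diverge on two axes at once. At the sequence level a family
splits into a "type-I" cluster (≥72% identity to a reference) and highly
divergent members (~26–48% identity) carrying ~32–36-residue linker
deletions and ~7–9-residue insertions downstream of the C-terminal domain.
At the structural level, molecular-dynamics ensembles show hinge-like
anti-correlated motion of the two domains, so conformational spread must be
separated from genuine fold divergence before homologs can be compared.

`confdiv` implements the full comparative pipeline for anyone analysing
such families from MD-derived multi-model PDB ensembles, FASTA sequences
and a multiple sequence alignment:

* **Sequence divergence** — global-alignment identity
  (BLOSUM62/11/1), type-I / distant / unassigned classification,
  Shannon-entropy conservation differentials
  (score `1 − H/log2 20`, mapped to reference numbering), indel blocks,
  "shs"/"phs" HTH-motif scans, sliding-window charge profiles, domain
  arithmetic.
* **Ensemble descriptors** — equilibration offset (20 ns default), frame
  sampling (25–95 ns / 10 ns → 8 conformations), per-frame RMSD and radius
  of gyration, median ± unscaled MAD summaries, exact/approximate pairwise
  Wilcoxon tests with Holm adjustment.
* **Within-ensemble dynamics** — dynamic cross-correlation matrices
  `C_ij = ⟨Δr_i·Δr_j⟩ / √(⟨|Δr_i|²⟩⟨|Δr_j|²⟩)` and Cartesian PCA of the
  superposed 3N coordinates, with principal-motion interpolation.
* **Cross-homolog structure** — MSA-guided TM-scores
  `(1/L) Σ 1/(1+(d_i/d0)²)`, `d0 = max(1.24(L−15)^⅓ − 1.8, 0.5)`, exhaustive
  pairwise conformation tables, iterative core-residue finding with a
  removal-trace knee, joint PCA with outlier ranking, and greedy progressive
  outlier removal.
* **Synthetic families** — a seeded generator that plants identities,
  indels, hinge motions and a stable core, so every stage has a
  ground-truth recovery test without any downloads.

Results come back as tibbles (with `tidy()`/`glance()` methods for fitted
objects) and each result type has an `autoplot()`/`plot_*()` companion.

## Worked example

Generate a seeded synthetic family (1 reference + 5 type-I + 2 distant
homologs, 21-frame hinge ensembles each) and push it through the main
stages:

```r
library(confdiv)

fam <- make_family(seed = 42)
hs  <- fam$homolog_set
hs
#> <homolog_set> 8 homologs (reference: ref), 8 with ensembles
#> # A tibble: 3 × 2
#>   group         n
#>   <chr>     <int>
#> 1 distant       2
#> 2 reference     1
#> 3 type-I        5
```

The planted indels of a distant member are recovered exactly, in reference
numbering (a 33-residue linker deletion adjacent to domain B, a 9-residue
insertion anchored after position 192):

```r
indel_blocks(hs$msa, "ref", "distant_01")
#> # A tibble: 2 × 3
#>   kind      reference_position length
#>   <chr>                  <int>  <int>
#> 1 deletion                 105     33
#> 2 insertion                192      9
```

Robust per-homolog compactness summaries (Rg in nm, median ± unscaled MAD
over the 17 frames after the 20 ns equilibration offset):

```r
ensemble_summary(hs, "rg")
#> # A tibble: 8 × 6
#>   homolog_id group     metric     n median    mad
#>   <chr>      <chr>     <chr>  <int>  <dbl>  <dbl>
#> 1 ref        reference rg        17   2.41 0.0198
#> 2 type1_01   type-I    rg        17   2.45 0.0204
#> ...
```

Within-ensemble dynamics of the reference homolog: the two HTH domains move
anti-correlated (hinge motion), and PC1 carries half the variance:

```r
ens <- hs$records$ensemble[[1]]
sup <- superpose_ensemble(apply_equilibration_offset(ens, 20), "mean")
inter_set_correlation(dccm(sup), set_a = 21:75, set_b = 138:192)
#> [1] -0.362
glance(trajectory_pca(sup))
#> # A tibble: 1 × 6
#>   n_frames n_residues n_components pc1_fraction pc2_fraction pc3_fraction
#>      <int>      <int>        <int>        <dbl>        <dbl>        <dbl>
#> 1       17        259           16        0.516       0.0412       0.0396
```

Cross-homolog comparison on the eight sampled conformations per homolog:
core residues concentrate in the stable N-side block, between-group
TM-scores sit far below within-group scores, and removing the two planted
divergent homologs raises the remaining median:

```r
sam <- hs
sam$records$ensemble <- lapply(sam$records$ensemble, sample_frames)
core_find(sam)
#> <core_find> 75 core positions (stop: knee, 219 removals traced)

tmb <- pairwise_matrix(sam, "between_homolog")
group_summary(tmb)
#> # A tibble: 2 × 5
#>   comparison_class     n median   min   max
#>   <chr>            <int>  <dbl> <dbl> <dbl>
#> 1 between_group      768  0.270 0.230 0.353
#> 2 within_group      1024  0.868 0.688 0.913

progressive_removal(tmb, 2)
#> # A tibble: 3 × 4
#>    step removed_id median_score n_pairs
#>   <int> <chr>             <dbl>   <int>
#> 1     0 <NA>              0.789    1792
#> 2     1 distant_01        0.848    1344
#> 3     2 distant_02        0.871     960
```

`run_pipeline(pipeline_config(input_dir, output_dir))` chains all stages
over an on-disk family (the layout written by `write_family()`) and emits
one TSV/JSON artifact per stage plus a run manifest keyed by a
configuration hash.

## Package layout

* `R/` — containers (`structure3d`, `ensemble`, `msa`, `homolog_set`),
  geometry, ensemble statistics, dynamics, structural comparison, sequence
  divergence, the synthetic generator, the pipeline, tidiers and plots.
* `tests/testthat/` — unit, property and recovery tests, including
  brute-force oracles (rotation-grid superposition and TM search,
  permutation Wilcoxon, exhaustive alignment enumeration).
* `vignettes/homolog-divergence.Rmd` — the methods vignette: models,
  conventions, generator design, numerical choices, limitations.
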