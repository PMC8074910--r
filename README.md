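# glycodiet

Comparative genomics of carbohydrate utilisation: does the glycoside
hydrolase (GH) gene repertoire of a gut symbiont track the **diet of its
host** rather than its own phylogeny?

`glycodiet` implements, as tested reusable R functions, the analysis
pipeline behind that question for genus-level surveys of bacterial type
strains (the motivating system is *Bifidobacterium*, whose growth depends
on host-diet carbohydrates such as milk oligosaccharides, plant xylans and
arabinans):

1. **Trait matrix** — pivot per-strain CAZyme annotations into a strain ×
   GH-family gene-count matrix; compute family prevalence (fraction of
   strains carrying ≥ 1 gene) and per-strain *GH content*
   (100 × GH genes / total CDS).
2. **Prevalence-threshold family sets** — 21 nested sets: families shared
   by 100 % of strains, then > 95 %, > 90 %, …, > 0 %. Set 17 is the
   "> 20 %" set.
3. **Clustering-stability selection** — hierarchically cluster strains
   (Ward on Euclidean distances by default) once per family set, cut at a
   fixed *k*, and select the highest-prevalence set whose partition is
   reproduced exactly (adjusted Rand index = 1) by the next two
   lower-threshold sets — the plateau where adding rarer families no
   longer changes the classification.
4. **Dietary-group statistics** — tie-corrected Kruskal–Wallis tests and
   Dunn's post hoc z comparisons of genome size, GH content and
   per-family counts across dietary groups (herbivore, frugivore,
   nectarivore, omnivore, …), plus a "characteristic family" high/low
   table.
5. **Phylogenetic signal** — Blomberg's
   *K* = (MSE₀/MSE) / E[MSE₀/MSE]₍BM₎ with a tip-shuffling permutation
   test, Moran's I phylogenetic correlograms over normalized patristic
   distance classes, and per-tip local Moran's I (LIPA) with conditional
   permutation p-values to find clades where GH content clusters.
6. **Synthetic data** — seeded generators for Yule trees,
   Brownian-motion / white-noise / clade-shifted traits, and
   diet-structured Poisson count datasets with tiered prevalence
   (including a planted > 20 % stability plateau), so every stage is
   validated against known ground truth. A core-genome COG-class ratio
   profiler (`cog_ratio_trend()`) covers pan/core-genome sweeps.

## Worked example

```r
library(glycodiet)

d <- simulate_diet_dataset(sim_config(plateau = TRUE, seed = 42))
m <- build_matrix(d$annotations, d$metadata)      # 84 strains x 40 families
prev <- family_prevalence(m)
sets <- build_family_sets(m)
res  <- select_stable_set(m, sets, k = 5)
res$selected_threshold_percent                    # 20
adjusted_rand(res$partitions[[17]], d$truth$planted_partition)  # 1

scan <- diet_association_scan(m, d$metadata, features = "genome_size")
tr    <- simulate_yule_tree(84, 1, seed = 7)
trait <- with(gh_content(m, d$metadata), setNames(gh_percent, strain_id))
blomberg_k_test(tr, trait, n_permutations = 999, seed = 11)
```

printed output:

```
selected set: 17  threshold: > 20 %  n families: 24
ARI vs planted groups: 1
genome size KW: H = 78.426, df = 4, p = 3.75e-16
GH content Blomberg K = 0.100, p = 0.533 (999 permutations)
```

Reading: the stability sweep lands on the planted > 20 % prevalence set
and its 5-group partition matches the planted dietary groups exactly;
genome sizes differ strongly across the diet groups (Kruskal–Wallis);
and because this dataset's gene counts were generated from diet structure
— not evolved along the tree — GH content shows no phylogenetic signal
(*K* near 0, permutation p ≫ 0.05) against an independently simulated
phylogeny.

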