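---
title: "Methods: GH repertoires, host diet, and phylogenetic signal"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: GH repertoires, host diet, and phylogenetic signal}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(glycodiet)
```

## The problem

Gut symbionts such as bifidobacteria live on the carbohydrates their host
eats. If diet drives the evolution of their carbohydrate-active enzymes,
then the glycoside hydrolase (GH) family repertoire of a strain should
classify strains by host feeding behaviour (herbivore, frugivore,
nectarivore, omnivore, ...) better than by the bacterial phylogeny.
`glycodiet` provides the statistical machinery for that comparison: a
strain-by-family count matrix as the central object, a principled way to
choose *which* families to classify on, rank-based group comparisons, and
phylogenetic-signal estimation for a continuous genomic trait (GH
content). Everything runs on plain TSV/Newick inputs of the shape
produced by standard annotation pipelines (a summarized dbCAN-style
table; any rooted tree with branch lengths), and a seeded simulator
generates structurally matched synthetic datasets for validation.

## Prevalence sets and stability selection

GH genes are non-essential and unevenly spread: typically a couple of
families are universal while a large "cloud" occurs in under 5 % of
strains. Classifying strains on all families lets rare families inject
noise; classifying on universal families alone leaves no information.
The pipeline therefore builds 21 nested family sets: the families shared
by **100 %** of strains (equality), then those with prevalence
**> 95 %**, **> 90 %**, ..., down to **> 0 %** in 5-point steps (set 17
is the "> 20 %" set). Thresholds are strict inequalities except the 100 %
set; prevalence is presence-based (count ≥ 1), since "shared by" refers
to possession of the family, not gene dosage. Both boundary behaviours
are unit-tested; a separate inclusive `prevalent_families()` screen
(default ≥ 80 %) exists for descriptive tables and is deliberately
distinct from the strict sweep.

For each set the strains are clustered (agglomerative, Euclidean distance
on raw counts with Ward linkage by default — the standard choice for
count-heatmap clustering; both are arguments) and the dendrogram is cut
at a fixed, user-supplied *k*. *k* is never auto-selected: the number of
groups is a scientific commitment read off the dendrogram, and
`suggest_k()` offers a silhouette-based hint without ever being applied
implicitly. "Two sets give the same classification" is formalized as
adjusted Rand index = 1.0 (agreement up to relabeling, to numerical
tolerance 1e-12). `select_stable_set()` walks from the strictest usable
set downward and returns the first whose partition is reproduced by the
next `m_consecutive = 2` sets — two because the stability of a threshold
is judged against the two sweeps below it; if no plateau exists the last
set is returned flagged `plateau_found = FALSE` rather than guessed.

Determinism: `build_matrix()` orders rows and columns lexicographically,
and `stats::hclust` is deterministic given its input order, so repeated
runs are bit-identical. We rely on `hclust`'s own tie handling rather
than re-implementing agglomeration with a bespoke tie rule; with
continuous distances from count data, exact merge ties essentially occur
only in degenerate fixtures, and determinism — the property that matters
— is already guaranteed by the fixed row order.

## Dietary-group statistics

Genome size, GH content (100 × GH genes / total CDS) and per-family
counts are compared across dietary groups with the tie-corrected
Kruskal–Wallis test (H referred to chi-square with g − 1 df) and Dunn's
post hoc z statistics on the pooled midranks,

$$z_{ab} = \frac{\bar R_a - \bar R_b}{\sqrt{\Big[\tfrac{N(N+1)}{12} -
\tfrac{\sum_t (t^3 - t)}{12(N-1)}\Big]\Big(\tfrac1{n_a}+\tfrac1{n_b}\Big)}},$$

two-sided against the standard normal. Pairwise p-values are
Holm-adjusted by default (Benjamini–Hochberg and unadjusted are options;
the underlying survey style reports per-family significance without
naming an adjustment, so the default is the conservative standard). The
per-family scan applies no cross-family correction by default, mirroring
per-family reporting; a BH option exists (`feature_adjust = "BH"`).
Groups contributing a single strain are retained (Kruskal–Wallis permits
n = 1) but listed in `singleton_groups`. A family is "characteristically
high" in a group when its Kruskal–Wallis p < α **and** that group has the
top mean rank **and** its Dunn-adjusted p beats α against more than half
of the other groups ("low" symmetric); the majority fraction is an
argument because published high/low tables state outcomes, not rules —
this is our declared formalization.

Degenerate data (all pooled values identical) define H = 0, p = 1 with a
warning, since the tie-correction denominator vanishes.

## Phylogenetic signal

With tree covariance $C_{ij}$ = depth of the MRCA of tips i and j
(`ape::vcv`), Blomberg's K is

$$K = \frac{\mathrm{MSE}_0/\mathrm{MSE}}
{\big[\mathrm{tr}(C) - n/(\mathbf{1}^\top C^{-1}\mathbf{1})\big]/(n-1)},
\qquad
\hat a = \frac{\mathbf{1}^\top C^{-1}x}{\mathbf{1}^\top C^{-1}\mathbf{1}},$$

with MSE₀ the ordinary and MSE the GLS mean squared deviation from
$\hat a$. K = 1 exactly on star trees for any non-constant trait; K → 0
for phylogeny-free traits. Solves use a Cholesky factorization of C (no
explicit inverse); an exactly singular C gets a one-off 1e-12 diagonal
nudge with a message, and a still-singular matrix is an error advising a
minimal branch-length epsilon. The permutation test shuffles trait values
across tips and uses the add-one estimator
p = (1 + #{K\* ≥ K}) / (1 + B), never exactly zero; B defaults to 999.
The implementation is cross-checked in the suite against
`picante::Kcalc` and `phytools::phylosig` to 1e-8.

Moran's I uses the textbook cross-product form; its permutation
expectation −1/(n−1) and the complete-graph identity are asserted
exactly. The correlogram normalizes patristic distances by their maximum
(so "distance 0.1" is comparable across trees — the scaled reading of
that cutoff is our choice and is documented), splits (0, 1] into
half-open classes, uses binary within-class neighbour weights, and draws
a two-sided permutation envelope per class; empty classes yield NA with a
warning. LIPA uses row-normalized inverse-patristic weights (the default
behaviour of the established R implementation of local phylogenetic
indicators), local values $I_i = (x_i-\bar x)/m_2 \sum_j w_{ij}(x_j-\bar
x)$, and conditional permutation p-values (tip i's value held fixed,
others shuffled), one-sided for positive association because the
scientific question is where trait values cluster. With shared
row-normalized weights, $\sum_i I_i = n \cdot I$ holds to 1e-9 and is
tested.

## The synthetic-data generator

The generator emulates the statistical structure the analysis assumes,
at the scale of the motivating survey — 84 strains, 72 families, 13
dietary groups by default:

* **Counts**: Poisson with base rate 1.5 and per-group effect
  multipliers (negative binomial via `overdispersion` for robustness
  checks, since real GH counts may be overdispersed; Poisson is the
  default for analytic transparency).
* **Prevalence tiers** mirror the empirical pattern (2 universal
  families, 8 at ~85 %, mid shells, 24 families under 5 %), with
  per-tier copy-number multipliers (5 / 3.5 / 2 / 1.5 / 1) so per-strain
  totals average ≈ 90 genes within the observed 33–166 range. Carrier
  strains are drawn at random at exactly the target fraction and
  guaranteed ≥ 1 gene, so realized prevalence hits the target up to
  rounding.
* **Genome sizes**: group means spread over 1.7–3.1 Mb (sd 150 kb,
  truncated positive), total CDS ≈ size/1100 bp plus noise — matching
  the observed 1.63–3.25 Mb span and typical gene density.
* **Trees**: forward Yule simulation (waiting time Exp(λk) at k
  lineages, uniform lineage split, final Exp(λn) stretch), so the mean
  root-to-tip depth has the closed form Σ_{k=2..n} 1/(λk) used as a
  distributional test. **Traits** are generated directly on the tree (BM
  preorder recursion or i.i.d. white noise) rather than routed through
  counts, isolating the K estimator from matrix noise.
* **Planted plateau** (`plateau = TRUE`, 5 groups): five strong marker
  families, one per group, at prevalence just above 20 % (all own-group
  strains plus a few count-1 strays; Poisson rate 25); one strong
  random-subset "decoy" family (rate 8) in every 5 % prevalence band
  above 25 %, so each stricter set differs from the next by a
  differently-structured family and keeps re-clustering; and weak
  presence-only cloud families below 20 %, so the > 20 %, > 15 % and
  > 10 % sets agree exactly. The markers dominate every set from > 20 %
  downward and pin the partition to the planted groups.
* **Planted clade trait**: white noise plus a +6 sd shift on one
  monophyletic clade of 4–6 tips of a 64-tip tree. The clade fraction is
  deliberately small (~8 %): an elevated clade drags the global mean, so
  with larger fractions the baseline tips sit coherently below the mean
  and exhibit *genuine* positive local autocorrelation — at 32 tips with
  a ~19 % clade the false-flag rate is inherently above 5 %. This is a
  property of local Moran statistics under mean shifts, not of the
  implementation, and is the reason the hotspot condition is stated at
  64 tips.

Everything is reproducible bit-for-bit from `seed` (the caller's RNG
state is saved and restored).

What passing these tests does **not** show about real data: counts are
(near-)Poisson and groups balanced round-robin, whereas real repertoires
are overdispersed, phylogenetically autocorrelated and unevenly sampled;
the planted plateau is a sharp construction, while real stability
plateaus can be approximate; and the simulated tree is independent of
the simulated counts, so the generator cannot by itself validate joint
diet-versus-phylogeny inference on data where both are entangled.

## Numerical choices and degenerate inputs

* Thresholds: strict `>` everywhere in the 21-set sweep except the 100 %
  set (`==`); boundary families (e.g. prevalence exactly 0.20) fall to
  the next set.
* ARI degenerate case (both partitions trivial): defined as 1.
* Family sets with < 2 families are skipped in the stability walk with a
  warning (their distance matrix is degenerate); all-identical rows are
  an error at k > 1.
* Permutation p-values use add-one estimators throughout; all
  permutation outputs are reproducible given (seed, B).
* Validation sizes in the test suite: identities at n = 16–24; K
  calibration 500 × 199 permutations on 16-tip trees; BM recovery 200 ×
  64 tips; plateau and clustering recovery 100 seeds each; LIPA 40
  planted clades at 499 permutations; null diet-scan calibration 500
  datasets. These run in about a minute total and give Monte-Carlo
  errors comfortably inside the asserted bands.

## Known limitations

* Only the statistics downstream of annotation are covered: genome
  annotation, orthologous clustering, CAZyme HMM assignment and tree
  inference are upstream tools, out of scope by design.
* Blomberg's K and Moran-type statistics only; no Pagel's λ or
  Abouheif's Cmean, and traits are univariate.
* Chi-square p-values for Kruskal–Wallis are asymptotic; with many tiny
  groups they are conservative (the null flag rate of the default-scale
  scan measures ≈ 0.035–0.04 at α = 0.05).
* Subspecies entries are atomic strain ids; no merging logic exists.
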