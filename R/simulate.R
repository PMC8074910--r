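#' Simulate a Yule (pure-birth) tree
#'
#' Forward simulation with exponential waiting times: starting from two
#' lineages at the root, each waiting time to the next speciation is
#' exponential with rate `birth_rate * k` (k = current number of lineages)
#' and a uniformly chosen lineage splits; after the n-th lineage appears a
#' final exponential stretch with rate `birth_rate * n` is appended. The
#' expected root-to-tip depth is therefore `sum(1 / (birth_rate * (2:n)))`.
#'
#' @param n_tips Number of tips (>= 3).
#' @param birth_rate Speciation rate (> 0; default 1).
#' @param seed Integer seed; the same seed reproduces the tree exactly.
#' @return A rooted, ultrametric binary `phylo` with zero-padded tip labels
#'   `s1..s<n>` (numbered in order of lineage creation), matching the
#'   strain ids emitted by [simulate_diet_dataset()] for equal sizes.
#' @export
simulate_yule_tree <- function(n_tips, birth_rate = 1, seed = NULL) {
  n_tips <- assert_scalar_count(n_tips, "n_tips", min = 3L)
  if (!is.numeric(birth_rate) || birth_rate <= 0) {
    stop_fmt("birth_rate must be > 0")
  }
  with_seed(seed, {
    # nodes: start time, children indices (NULL = active lineage), end time
    nodes <- list(list(start = 0, children = c(2L, 3L), end = 0),
                  list(start = 0, children = NULL, end = NA_real_),
                  list(start = 0, children = NULL, end = NA_real_))
    active <- c(2L, 3L)
    t <- 0
    k <- 2L
    while (k < n_tips) {
      t <- t + stats::rexp(1, rate = birth_rate * k)
      j <- active[sample.int(length(active), 1L)]
      nodes[[j]]$end <- t
      id1 <- length(nodes) + 1L
      id2 <- length(nodes) + 2L
      nodes[[j]]$children <- c(id1, id2)
      nodes[[id1]] <- list(start = t, children = NULL, end = NA_real_)
      nodes[[id2]] <- list(start = t, children = NULL, end = NA_real_)
      active <- c(setdiff(active, j), id1, id2)
      k <- k + 1L
    }
    t_end <- t + stats::rexp(1, rate = birth_rate * n_tips)
    for (j in active) nodes[[j]]$end <- t_end
    tip_counter <- 0L
    newick <- function(idx) {
      nd <- nodes[[idx]]
      len <- nd$end - nd$start
      if (is.null(nd$children)) {
        tip_counter <<- tip_counter + 1L
        sprintf("s%0*d:%.10f", nchar(n_tips), tip_counter, len)
      } else {
        sprintf("(%s,%s):%.10f", newick(nd$children[1]), newick(nd$children[2]),
                len)
      }
    }
    txt <- sprintf("(%s,%s);", newick(2L), newick(3L))
    ape::read.tree(text = txt)
  })
}

#' Simulate a Brownian-motion trait on a tree
#'
#' Preorder recursion from the root: each child value is its parent value
#' plus a Normal(0, `sigma2` x branch length) increment; tip values are
#' returned.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param sigma2 Brownian rate (diffusion variance per unit branch length).
#' @param root_value Trait value at the root (default 0).
#' @param seed Integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_bm <- function(tree, sigma2, root_value = 0, seed = NULL) {
  if (!is.numeric(sigma2) || sigma2 <= 0) stop_fmt("sigma2 must be > 0")
  tree <- validate_tree(tree)
  with_seed(seed, {
    ord <- ape::reorder.phylo(tree, "cladewise")  # parents before children
    n <- ape::Ntip(tree)
    val <- numeric(n + tree$Nnode)
    val[n + 1L] <- root_value
    for (e in seq_len(nrow(ord$edge))) {
      parent <- ord$edge[e, 1]
      child <- ord$edge[e, 2]
      val[child] <- val[parent] +
        stats::rnorm(1, 0, sqrt(sigma2 * ord$edge.length[e]))
    }
    stats::setNames(val[seq_len(n)], tree$tip.label)
  })
}

#' Simulate a white-noise (phylogeny-free) trait
#'
#' Tip values drawn i.i.d. Normal, carrying no phylogenetic signal; the
#' null model for signal statistics.
#'
#' @param tree A `phylo` (only the tip labels are used).
#' @param sd Standard deviation (default 1).
#' @param mean Mean (default 0).
#' @param seed Integer seed.
#' @return Named numeric vector over the tips.
#' @export
simulate_white_noise <- function(tree, sd = 1, mean = 0, seed = NULL) {
  with_seed(seed, {
    stats::setNames(stats::rnorm(ape::Ntip(tree), mean, sd), tree$tip.label)
  })
}

#' Simulate a trait elevated on one clade
#'
#' White-noise baseline with a constant shift added to every tip of one
#' monophyletic clade: the planted "hotspot" configuration for local
#' phylogenetic-association tests. The clade is the first internal node
#' (in ape node order, root excluded) whose tip count falls in
#' `clade_size`; an error is raised if the tree has no such clade.
#'
#' @param tree A `phylo`.
#' @param clade_size Two-element range of acceptable clade tip counts
#'   (default `c(4, 6)`).
#' @param shift Trait shift added on the clade, in units of the baseline
#'   standard deviation (default 6).
#' @param sd Baseline white-noise standard deviation (default 1).
#' @param seed Integer seed.
#' @return A list with `trait` (named vector) and `clade_tips` (character).
#' @export
simulate_clade_trait <- function(tree, clade_size = c(4, 6), shift = 6,
                                 sd = 1, seed = NULL) {
  tree <- validate_tree(tree)
  n <- ape::Ntip(tree)
  clade <- NULL
  for (nd in setdiff((n + 1L):(n + tree$Nnode), n + 1L)) {
    tips <- ape::extract.clade(tree, nd)$tip.label
    if (length(tips) >= clade_size[1] && length(tips) <= clade_size[2]) {
      clade <- tips
      break
    }
  }
  if (is.null(clade)) {
    stop_fmt("tree has no clade with %d-%d tips", clade_size[1], clade_size[2])
  }
  trait <- simulate_white_noise(tree, sd = sd, seed = seed)
  trait[clade] <- trait[clade] + shift * sd
  list(trait = trait, clade_tips = clade)
}

#' Configuration for the diet-structured dataset simulator
#'
#' Defaults mirror the scale of a genus-level type-strain survey: 84
#' strains, 72 gene families, 13 dietary groups, and tiered prevalence with
#' a couple of universal families, a common tier, mid-prevalence shells and
#' a large "cloud" of families seen in under 5% of strains.
#'
#' @param n_strains,n_families,n_groups Dataset dimensions.
#' @param base_rate Poisson mean gene count for an unaffected, carried
#'   family (default 1.2, giving realistic per-strain totals near 90).
#' @param effect_multipliers Optional `n_groups x n_families` matrix of
#'   positive rate multipliers (rownames ignored; entry `[g, f]` scales the
#'   Poisson mean of family f in strains of group g). `NULL` = all 1, the
#'   null configuration. See [planted_effect_multipliers()].
#' @param prevalence_tiers Data frame with columns `fraction` (of families;
#'   must sum to <= 1), `prevalence` (target fraction of carrier strains)
#'   and optionally `rate_multiplier` (scales the Poisson mean for the
#'   tier's families: widespread families such as GH13 also tend to carry
#'   more gene copies). Families are assigned to tiers in order; families
#'   beyond the tiers are left unthinned. `NULL` disables thinning.
#' @param genome_size_means Per-group mean genome sizes in bp (recycled to
#'   `n_groups`; default an even spread over 1.7--3.1 Mb).
#' @param genome_size_sd Within-group genome-size standard deviation (bp).
#' @param cds_per_bp Expected coding genes per bp (default 1/1100).
#' @param overdispersion If > 0, counts are negative binomial with this
#'   Gamma heterogeneity (size = 1/overdispersion) instead of Poisson.
#' @param plateau If `TRUE`, plant a clustering-stability plateau at the
#'   >20% prevalence set: five strong group-marker families just above 20%
#'   prevalence, decoy families spread over every higher-prevalence band
#'   (so consecutive stricter sets keep re-clustering differently) and weak
#'   low-prevalence cloud families below 20% (so the >20%, >15% and >10%
#'   sets agree). Forces `n_groups = 5`.
#' @param seed Integer seed.
#' @return A `sim_config` list.
#' @export
sim_config <- function(n_strains = 84, n_families = 72, n_groups = 13,
                       base_rate = 1.5,
                       effect_multipliers = NULL,
                       prevalence_tiers = data.frame(
                         fraction = c(2, 8, 21, 17, 24) / 72,
                         prevalence = c(1, 0.85, 0.45, 0.22, 0.035),
                         rate_multiplier = c(5, 3.5, 2, 1.5, 1)),
                       genome_size_means = NULL,
                       genome_size_sd = 1.5e5,
                       cds_per_bp = 1 / 1100,
                       overdispersion = 0,
                       plateau = FALSE,
                       seed = 1L) {
  n_strains <- assert_scalar_count(n_strains, "n_strains", min = 4L)
  n_families <- assert_scalar_count(n_families, "n_families", min = 2L)
  n_groups <- assert_scalar_count(n_groups, "n_groups", min = 2L)
  if (plateau) n_groups <- 5L
  if (base_rate <= 0) stop_fmt("base_rate must be > 0")
  if (!is.null(prevalence_tiers)) {
    if (!all(c("fraction", "prevalence") %in% names(prevalence_tiers))) {
      stop_fmt("prevalence_tiers needs 'fraction' and 'prevalence' columns")
    }
    if (sum(prevalence_tiers$fraction) > 1 + 1e-9) {
      stop_fmt("tier fractions must sum to at most 1")
    }
    if (any(prevalence_tiers$prevalence <= 0 | prevalence_tiers$prevalence > 1)) {
      stop_fmt("tier prevalences must lie in (0, 1]")
    }
  }
  if (!is.null(effect_multipliers)) {
    effect_multipliers <- as.matrix(effect_multipliers)
    if (nrow(effect_multipliers) != n_groups ||
        ncol(effect_multipliers) != n_families) {
      stop_fmt("effect_multipliers must be %d x %d", n_groups, n_families)
    }
    if (any(effect_multipliers <= 0)) stop_fmt("multipliers must be > 0")
  }
  if (is.null(genome_size_means)) {
    genome_size_means <- seq(1.7e6, 3.1e6, length.out = n_groups)
  }
  genome_size_means <- rep_len(genome_size_means, n_groups)
  structure(list(n_strains = n_strains, n_families = n_families,
                 n_groups = n_groups, base_rate = base_rate,
                 effect_multipliers = effect_multipliers,
                 prevalence_tiers = prevalence_tiers,
                 genome_size_means = genome_size_means,
                 genome_size_sd = genome_size_sd,
                 cds_per_bp = cds_per_bp,
                 overdispersion = overdispersion,
                 plateau = isTRUE(plateau),
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Block effect-multiplier matrix for planted group signatures
#'
#' Gives each group `families_per_group` consecutive signature families at
#' rate multiplier `multiplier` (all other entries 1): the standard
#' "strong planted effect" configuration for recovery tests.
#'
#' @param n_groups,n_families Dimensions (must allow
#'   `n_groups * families_per_group <= n_families`).
#' @param families_per_group Signature families per group (default 3).
#' @param multiplier Rate multiplier on signature families (default 6).
#' @return An `n_groups x n_families` matrix.
#' @export
planted_effect_multipliers <- function(n_groups, n_families,
                                       families_per_group = 3,
                                       multiplier = 6) {
  if (n_groups * families_per_group > n_families) {
    stop_fmt("not enough families for %d signature families per group",
             families_per_group)
  }
  m <- matrix(1, n_groups, n_families)
  for (g in seq_len(n_groups)) {
    cols <- ((g - 1) * families_per_group + 1):(g * families_per_group)
    m[g, cols] <- multiplier
  }
  m
}

strain_labels <- function(n) sprintf("s%0*d", nchar(n), seq_len(n))
family_labels <- function(n) sprintf("F%0*d", nchar(n), seq_len(n))

#' Simulate a diet-structured annotation dataset
#'
#' Emits an annotation table, strain metadata and a ground-truth record
#' with the statistical structure the downstream analysis assumes: strains
#' assigned round-robin to dietary groups; gene counts Poisson with
#' per-group rate multipliers; family presence thinned to tiered prevalence
#' targets (carrier strains are guaranteed at least one gene, so the
#' empirical prevalence hits the target exactly up to rounding);
#' group-structured genome sizes with proportional coding-gene totals.
#' With `plateau = TRUE` in the config the family structure instead plants
#' a clustering-stability plateau at the >20% prevalence set (see
#' [sim_config()]).
#'
#' @param config A [sim_config()].
#' @return A list with `annotations` (an `annotation_table` of the nonzero
#'   counts), `metadata` (a `strain_metadata` table) and `truth` (class
#'   `sim_truth`: `planted_partition`, `affected_family_ids`,
#'   `plateau_threshold_percent`, `group_of` and the realized
#'   `prevalence_targets`).
#' @export
simulate_diet_dataset <- function(config = sim_config()) {
  if (!inherits(config, "sim_config")) stop_fmt("expected a 'sim_config'")
  with_seed(config$seed, {
    n <- config$n_strains
    nf <- config$n_families
    ng <- config$n_groups
    strains <- strain_labels(n)
    group_idx <- ((seq_len(n) - 1L) %% ng) + 1L
    group_names <- sprintf("diet%0*d", nchar(ng), seq_len(ng))
    if (config$plateau) {
      sim <- simulate_plateau_counts(config, strains, group_idx)
    } else {
      sim <- simulate_tiered_counts(config, strains, group_idx)
    }
    counts <- sim$counts

    gsize <- round(truncnorm_pos(n, config$genome_size_means[group_idx],
                                 config$genome_size_sd))
    cds <- pmax(rowSums(counts) + 50L,
                round(gsize * config$cds_per_bp + stats::rnorm(n, 0, 40)))
    gc <- pmin(70, pmax(45, stats::rnorm(n, 60.8, 3)))
    metadata <- as_strain_metadata(data.frame(
      strain_id = strains,
      diet_group = group_names[group_idx],
      host_group = sprintf("host%d", ((group_idx - 1L) %% 4L) + 1L),
      genome_size_bp = gsize,
      gc_percent = gc,
      total_cds = as.integer(cds),
      stringsAsFactors = FALSE))

    keep <- counts > 0L
    ann <- data.frame(
      strain_id = rep(strains, times = rowSums(keep)),
      family_id = colnames(counts)[unlist(apply(keep, 1, which), use.names = FALSE)],
      gene_count = as.integer(t(counts)[t(keep)]),
      stringsAsFactors = FALSE)
    # row-major extraction above: rebuild in strain order for tidiness
    ord <- order(ann$strain_id, ann$family_id)
    ann <- as_annotation_table(ann[ord, , drop = FALSE])

    truth <- structure(list(
      planted_partition = new_partition(stats::setNames(group_idx, strains),
                                        ng),
      group_of = stats::setNames(group_names[group_idx], strains),
      affected_family_ids = sim$affected,
      plateau_threshold_percent = sim$plateau_threshold,
      prevalence_targets = sim$prevalence_targets,
      trait_model = NA_character_),
      class = "sim_truth")
    list(annotations = ann, metadata = metadata, truth = truth)
  })
}

truncnorm_pos <- function(n, mean, sd) {
  x <- stats::rnorm(n, mean, sd)
  while (any(x <= 0)) {
    bad <- x <= 0
    x[bad] <- stats::rnorm(sum(bad), mean[bad], sd)
  }
  x
}

rcounts <- function(n, lambda, overdispersion) {
  if (overdispersion > 0) {
    stats::rnbinom(n, size = 1 / overdispersion, mu = lambda)
  } else {
    stats::rpois(n, lambda)
  }
}

# Tiered-prevalence counts: families are carried by a random subset of
# strains sized to the tier's target prevalence; carriers drawing a zero
# count are bumped to one gene so the empirical prevalence equals the
# target up to rounding.
simulate_tiered_counts <- function(config, strains, group_idx) {
  n <- length(strains)
  nf <- config$n_families
  fams <- family_labels(nf)
  mult <- config$effect_multipliers
  lam <- matrix(config$base_rate, n, nf)
  if (!is.null(mult)) lam <- lam * mult[group_idx, , drop = FALSE]
  counts <- matrix(rcounts(n * nf, lam, config$overdispersion), n, nf,
                   dimnames = list(strains, fams))
  prevalence_targets <- rep(NA_real_, nf)
  tiers <- config$prevalence_tiers
  if (!is.null(tiers)) {
    if (is.null(tiers$rate_multiplier)) tiers$rate_multiplier <- 1
    f_next <- 1L
    for (ti in seq_len(nrow(tiers))) {
      n_tier <- round(tiers$fraction[ti] * nf)
      if (n_tier == 0) next
      f_idx <- f_next:min(nf, f_next + n_tier - 1L)
      f_next <- f_next + n_tier
      q <- tiers$prevalence[ti]
      n_carriers <- max(1L, round(q * n))
      if (tiers$rate_multiplier[ti] != 1) {
        counts[, f_idx] <- rcounts(n * length(f_idx),
                                   lam[, f_idx] * tiers$rate_multiplier[ti],
                                   config$overdispersion)
      }
      for (f in f_idx) {
        carriers <- sample.int(n, n_carriers)
        counts[-carriers, f] <- 0L
        zero_carriers <- carriers[counts[carriers, f] == 0L]
        counts[zero_carriers, f] <- 1L
        prevalence_targets[f] <- n_carriers / n
      }
    }
  }
  affected <- if (is.null(mult)) character(0) else {
    fams[apply(mult, 2, function(col) any(col != 1))]
  }
  list(counts = counts, affected = affected,
       plateau_threshold = NA_real_,
       prevalence_targets = stats::setNames(prevalence_targets, fams))
}

# Plateau-planting counts (5 groups). Family blocks:
#  * core: carried by everyone, weak iid counts -- the 100% set alone has no
#    group information;
#  * decoys: one strong random-subset family per 5%-prevalence band from
#    (95,100) down to (25,30), so each stricter-threshold set differs from
#    the next by one strong, differently structured family and their
#    clusterings keep changing;
#  * markers: five strong families, one per group, at prevalence just above
#    20% (all own-group strains plus a few count-1 strays), which dominate
#    every set from >20% downward and pin the clustering to the planted
#    five groups;
#  * cloud: weak presence-only families below 20% prevalence, so the >20%,
#    >15% and >10% (and lower) sets agree exactly.
simulate_plateau_counts <- function(config, strains, group_idx) {
  n <- length(strains)
  marker_rate <- 25
  decoy_rate <- 8
  core_rate <- 2
  n_core <- 4L
  decoy_q <- (seq(95, 25, by = -5) + 2.5) / 100   # one per band, 15 decoys
  cloud_q <- rep(c(0.175, 0.125, 0.075, 0.03), each = 4L)
  nf <- n_core + length(decoy_q) + 5L + length(cloud_q)
  fams <- family_labels(nf)
  counts <- matrix(0L, n, nf, dimnames = list(strains, fams))
  prevalence_targets <- rep(NA_real_, nf)
  f <- 0L
  for (i in seq_len(n_core)) {
    f <- f + 1L
    counts[, f] <- 1L + stats::rpois(n, core_rate)
    prevalence_targets[f] <- 1
  }
  for (q in decoy_q) {
    f <- f + 1L
    carriers <- sample.int(n, round(q * n))
    counts[carriers, f] <- 1L + stats::rpois(length(carriers), decoy_rate)
    prevalence_targets[f] <- round(q * n) / n
  }
  marker_ids <- character(5)
  n_stray <- max(1L, ceiling(0.21 * n) - min(table(group_idx)))
  for (g in 1:5) {
    f <- f + 1L
    marker_ids[g] <- fams[f]
    own <- which(group_idx == g)
    stray <- utils::head(which(group_idx == (g %% 5L) + 1L), n_stray)
    counts[own, f] <- 1L + stats::rpois(length(own), marker_rate)
    counts[stray, f] <- 1L
    prevalence_targets[f] <- (length(own) + length(stray)) / n
  }
  for (q in cloud_q) {
    f <- f + 1L
    carriers <- sample.int(n, max(1L, round(q * n)))
    counts[carriers, f] <- 1L
    prevalence_targets[f] <- max(1L, round(q * n)) / n
  }
  list(counts = counts, affected = marker_ids,
       plateau_threshold = 20,
       prevalence_targets = stats::setNames(prevalence_targets, fams))
}
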