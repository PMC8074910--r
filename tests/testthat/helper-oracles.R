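# Independent from-definition oracles and small fixture builders used
# across the test files. Everything here is deliberately written the slow,
# literal way so it cannot share code paths with the package.

# Adjusted Rand index by explicit pair counting over all item pairs.
ari_oracle <- function(a, b) {
  stopifnot(identical(names(a), names(b)))
  n <- length(a)
  n11 <- n00 <- n10 <- n01 <- 0
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      same_a <- a[i] == a[j]
      same_b <- b[i] == b[j]
      if (same_a && same_b) n11 <- n11 + 1
      else if (!same_a && !same_b) n00 <- n00 + 1
      else if (same_a) n10 <- n10 + 1
      else n01 <- n01 + 1
    }
  }
  total <- n11 + n00 + n10 + n01
  expected <- (n11 + n10) * (n11 + n01) / total
  max_index <- ((n11 + n10) + (n11 + n01)) / 2
  if (max_index == expected) return(1)
  (n11 - expected) / (max_index - expected)
}

# Midranks computed literally: for each value, 1 + number smaller + half
# the number of equal others.
midranks_oracle <- function(x) {
  sapply(seq_along(x), function(i) {
    1 + sum(x < x[i]) + (sum(x == x[i]) - 1) / 2
  })
}

# Tie-corrected Kruskal-Wallis H from the definition.
kw_oracle <- function(values_by_group) {
  pooled <- unlist(values_by_group, use.names = FALSE)
  N <- length(pooled)
  r <- midranks_oracle(pooled)
  grp <- rep(seq_along(values_by_group), lengths(values_by_group))
  h <- 0
  for (g in seq_along(values_by_group)) {
    rg <- r[grp == g]
    h <- h + length(rg) * (mean(rg) - (N + 1) / 2)^2
  }
  h <- 12 * h / (N * (N + 1))
  tie_sizes <- as.numeric(table(pooled))
  correction <- 1 - sum(tie_sizes^3 - tie_sizes) / (N^3 - N)
  h / correction
}

# Dunn pairwise z from the definition.
dunn_oracle <- function(values_by_group) {
  pooled <- unlist(values_by_group, use.names = FALSE)
  N <- length(pooled)
  r <- midranks_oracle(pooled)
  grp <- rep(seq_along(values_by_group), lengths(values_by_group))
  tie_sizes <- as.numeric(table(pooled))
  v <- N * (N + 1) / 12 - sum(tie_sizes^3 - tie_sizes) / (12 * (N - 1))
  out <- NULL
  g <- length(values_by_group)
  for (a in seq_len(g - 1)) {
    for (b in (a + 1):g) {
      ra <- r[grp == a]; rb <- r[grp == b]
      z <- (mean(ra) - mean(rb)) /
        sqrt(v * (1 / length(ra) + 1 / length(rb)))
      out <- rbind(out, data.frame(a = a, b = b, z = z))
    }
  }
  out
}

# MRCA depth of a tip pair by intersecting root paths edge by edge.
mrca_depth_oracle <- function(tree, tip_a, tip_b) {
  root <- ape::Ntip(tree) + 1L
  path_to_root <- function(tip) {
    node <- which(tree$tip.label == tip)
    path <- node
    while (node != root) {
      node <- tree$edge[tree$edge[, 2] == node, 1]
      path <- c(path, node)
    }
    path
  }
  pa <- path_to_root(tip_a)
  pb <- path_to_root(tip_b)
  mrca <- intersect(pa, pb)[1]
  depth <- 0
  node <- mrca
  while (node != root) {
    e <- which(tree$edge[, 2] == node)
    depth <- depth + tree$edge.length[e]
    node <- tree$edge[e, 1]
  }
  depth
}

# Patristic distance by summing branch lengths along the two root paths
# below the MRCA.
patristic_oracle <- function(tree, tip_a, tip_b) {
  depth_of <- function(tip) {
    root <- ape::Ntip(tree) + 1L
    node <- which(tree$tip.label == tip)
    depth <- 0
    while (node != root) {
      e <- which(tree$edge[, 2] == node)
      depth <- depth + tree$edge.length[e]
      node <- tree$edge[e, 1]
    }
    depth
  }
  depth_of(tip_a) + depth_of(tip_b) - 2 * mrca_depth_oracle(tree, tip_a, tip_b)
}

star_tree <- function(n, branch = 1) {
  ape::read.tree(text = paste0(
    "(", paste(sprintf("t%d:%g", seq_len(n), branch), collapse = ","), ");"))
}

random_partition <- function(n, max_k = 4) {
  stats::setNames(sample.int(max_k, n, replace = TRUE),
                  sprintf("i%d", seq_len(n)))
}

write_lines_tsv <- function(lines) {
  path <- tempfile(fileext = ".tsv")
  writeLines(lines, path)
  path
}
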