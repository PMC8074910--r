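#' Brownian-motion covariance matrix of a rooted tree
#'
#' `C[i, j]` is the shared root-to-tip path length of tips i and j (the
#' depth of their most recent common ancestor); the diagonal holds the
#' root-to-tip distances. This is the expected tip covariance (up to the
#' rate) of a Brownian-motion trait evolving along the tree.
#'
#' @param tree A rooted `phylo` with branch lengths and >= 3 tips.
#' @return A symmetric positive semidefinite matrix with tip labels as
#'   dimnames.
#' @export
phylo_cov <- function(tree) {
  tree <- validate_tree(tree)
  ape::vcv(tree)
}

check_trait <- function(trait, tree) {
  if (!is.numeric(trait) || is.null(names(trait))) {
    stop_fmt("trait must be a named numeric vector (names = tip labels)")
  }
  if (!setequal(names(trait), tree$tip.label) ||
      length(trait) != ape::Ntip(tree)) {
    stop_fmt("trait names must match the tree tip labels exactly")
  }
  if (anyNA(trait) || any(!is.finite(trait))) stop_fmt("trait values must be finite")
  trait[tree$tip.label]
}

# Factor C once; returns a function x -> K plus bookkeeping shared by the
# point estimate and the permutation test.
k_machine <- function(tree, trait) {
  x <- check_trait(trait, tree)
  if (stats::var(x) == 0) stop_fmt("trait has zero variance")
  C <- phylo_cov(tree)
  n <- length(x)
  Cinv <- tryCatch(chol2inv(chol(C)), error = function(e) NULL)
  if (is.null(Cinv)) {
    # exact singularity (e.g. duplicated tips at zero distance); nudge the
    # diagonal minimally rather than fail outright
    message("covariance matrix numerically singular; adding 1e-12 to diagonal")
    Cinv <- tryCatch(chol2inv(chol(C + diag(1e-12, n))), error = function(e) {
      stop_fmt(paste("singular phylogenetic covariance; consider a minimal",
                     "positive branch-length epsilon on zero-length edges"))
    })
  }
  ones <- rep(1, n)
  Cinv1 <- Cinv %*% ones
  denom1 <- sum(Cinv1)  # 1' Cinv 1
  expected_ratio <- (sum(diag(C)) - n / denom1) / (n - 1)
  k_of <- function(xx) {
    ahat <- sum(Cinv1 * xx) / denom1
    dev <- xx - ahat
    mse0 <- sum(dev^2) / (n - 1)
    mse <- sum(dev * (Cinv %*% dev)) / (n - 1)
    (mse0 / mse) / expected_ratio
  }
  list(x = x, k_of = k_of)
}

#' Blomberg's K phylogenetic signal statistic
#'
#' The ratio of the observed mean squared trait deviation (from the
#' phylogenetically weighted ancestral mean) to its GLS counterpart under
#' the tree covariance, scaled by the value this ratio takes in expectation
#' under Brownian motion. K near 1 indicates Brownian-like signal; K near 0
#' indicates trait values independent of the phylogeny. On a star tree
#' K = 1 for every non-constant trait.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param trait Named numeric vector over the tree tips (e.g. GH content
#'   per strain, see [gh_content()]).
#' @return Blomberg's K (single non-negative number).
#' @export
blomberg_k <- function(tree, trait) {
  m <- k_machine(tree, trait)
  m$k_of(m$x)
}

#' Permutation test for Blomberg's K
#'
#' Shuffles the trait values across the tips and recomputes K; the one-sided
#' p-value uses the add-one estimator
#' `p = (1 + #\{K_perm >= K_obs\}) / (1 + n_permutations)`, so it is never
#' exactly zero. Fully reproducible given the seed.
#'
#' @param tree A rooted `phylo`.
#' @param trait Named numeric trait vector over the tips.
#' @param n_permutations Number of permutations (>= 99; default 999).
#' @param seed Integer seed for the shuffles.
#' @return A `signal_result`: `K`, `p_value`, `n_permutations`, `seed`
#'   and the permuted `K_permuted` values.
#' @export
blomberg_k_test <- function(tree, trait, n_permutations = 999, seed = 1L) {
  n_permutations <- assert_scalar_count(n_permutations, "n_permutations",
                                        min = 99L)
  m <- k_machine(tree, trait)
  k_obs <- m$k_of(m$x)
  k_perm <- with_seed(seed, {
    vapply(seq_len(n_permutations), function(b) m$k_of(sample(m$x)),
           numeric(1))
  })
  p <- (1 + sum(k_perm >= k_obs)) / (1 + n_permutations)
  structure(list(K = k_obs, p_value = p,
                 n_permutations = n_permutations, seed = as.integer(seed),
                 K_permuted = k_perm),
            class = "signal_result")
}

#' Proximity weights between tips from patristic distance
#'
#' `W[i, j] = 1 / d(i, j)` with a zero diagonal, where d is the patristic
#' (branch-length path) distance; optionally each row is normalized to sum
#' to 1. This is the proximity structure used for local phylogenetic
#' autocorrelation.
#'
#' @param tree A rooted `phylo` with branch lengths.
#' @param method Currently `"inverse_patristic"`.
#' @param row_normalize Normalize each row to sum to 1 (default TRUE).
#' @return An n x n weight matrix with tip-label dimnames.
#' @export
proximity_weights <- function(tree, method = "inverse_patristic",
                              row_normalize = TRUE) {
  method <- match.arg(method, "inverse_patristic")
  tree <- validate_tree(tree)
  d <- ape::cophenetic.phylo(tree)
  off <- d[upper.tri(d)]
  if (any(off == 0)) stop_fmt("tips at zero patristic distance; cannot invert")
  W <- 1 / d
  diag(W) <- 0
  if (row_normalize) W <- W / rowSums(W)
  W
}

#' Global Moran's I autocorrelation of a trait
#'
#' \deqn{I = \frac{n}{\sum_{ij} w_{ij}} \cdot
#'   \frac{\sum_{ij} w_{ij}(x_i-\bar x)(x_j - \bar x)}{\sum_i (x_i-\bar x)^2}}
#' Expectation under no autocorrelation is `-1/(n-1)`.
#'
#' @param trait Named numeric vector.
#' @param W Weight matrix with matching dimnames (zero diagonal).
#' @return Moran's I (single number).
#' @export
moran_i <- function(trait, W) {
  if (!is.matrix(W) || nrow(W) != ncol(W)) stop_fmt("W must be square")
  if (!is.null(names(trait)) && !is.null(rownames(W))) {
    if (!setequal(names(trait), rownames(W))) {
      stop_fmt("trait names and weight dimnames differ")
    }
    trait <- trait[rownames(W)]
  }
  if (length(trait) != nrow(W)) stop_fmt("trait and W dimensions differ")
  sw <- sum(W)
  if (sw == 0) stop_fmt("weight matrix is all zero")
  z <- trait - mean(trait)
  ss <- sum(z^2)
  if (ss == 0) stop_fmt("trait has zero variance")
  n <- length(z)
  (n / sw) * sum(W * tcrossprod(z)) / ss
}

#' Phylogenetic correlogram of Moran's I across distance classes
#'
#' Patristic distances are scaled to a maximum of 1; the unit interval is
#' split into `n_classes` half-open classes (low, high], each defining
#' binary neighbor weights (pairs whose scaled distance falls in the class)
#' for Moran's I. A two-sided permutation envelope per class gives the
#' significance: observed I outside the (alpha/2, 1-alpha/2) quantiles of
#' the permuted values.
#'
#' @param tree A rooted `phylo`.
#' @param trait Named numeric trait over the tips.
#' @param n_classes Number of distance classes (default 10).
#' @param n_permutations Permutations for the envelope (default 199).
#' @param seed Integer seed.
#' @param alpha Envelope level (default 0.05).
#' @return A `correlogram_result` with a per-class data frame `classes`
#'   (`low`, `high`, `n_pairs`, `I`, `lower`, `upper`, `significant`) and
#'   the run parameters. Empty classes carry NA with a warning.
#' @export
correlogram <- function(tree, trait, n_classes = 10, n_permutations = 199,
                        seed = 1L, alpha = 0.05) {
  n_classes <- assert_scalar_count(n_classes, "n_classes", min = 2L)
  n_permutations <- assert_scalar_count(n_permutations, "n_permutations",
                                        min = 99L)
  tree <- validate_tree(tree)
  x <- check_trait(trait, tree)
  d <- ape::cophenetic.phylo(tree)
  d <- d / max(d)
  edges <- seq(0, 1, length.out = n_classes + 1)
  n <- length(x)
  Ws <- vector("list", n_classes)
  for (cl in seq_len(n_classes)) {
    W <- (d > edges[cl] & d <= edges[cl + 1]) * 1
    diag(W) <- 0
    Ws[[cl]] <- W
  }
  n_pairs <- vapply(Ws, function(W) sum(W) / 2, numeric(1))
  obs <- rep(NA_real_, n_classes)
  for (cl in seq_len(n_classes)) {
    if (n_pairs[cl] == 0) {
      warning(sprintf("distance class %d is empty", cl), call. = FALSE)
      next
    }
    obs[cl] <- moran_i(x, Ws[[cl]])
  }
  perm <- with_seed(seed, {
    t(vapply(seq_len(n_permutations), function(b) {
      xp <- stats::setNames(sample(unname(x)), names(x))
      vapply(seq_len(n_classes), function(cl) {
        if (n_pairs[cl] == 0) NA_real_ else moran_i(xp, Ws[[cl]])
      }, numeric(1))
    }, numeric(n_classes)))
  })
  lower <- apply(perm, 2, function(v) {
    if (all(is.na(v))) NA_real_ else stats::quantile(v, alpha / 2, na.rm = TRUE)
  })
  upper <- apply(perm, 2, function(v) {
    if (all(is.na(v))) NA_real_ else stats::quantile(v, 1 - alpha / 2, na.rm = TRUE)
  })
  classes <- data.frame(low = edges[-length(edges)], high = edges[-1],
                        n_pairs = n_pairs, I = obs,
                        lower = lower, upper = upper,
                        significant = !is.na(obs) & (obs < lower | obs > upper),
                        row.names = NULL)
  structure(list(classes = classes, n_permutations = n_permutations,
                 seed = as.integer(seed), alpha = alpha),
            class = "correlogram_result")
}

#' Local indicators of phylogenetic association (LIPA)
#'
#' Per-tip local Moran's I,
#' \deqn{I_i = \frac{x_i - \bar x}{m_2} \sum_j w_{ij}(x_j - \bar x), \qquad
#'   m_2 = \frac{1}{n}\sum_k (x_k - \bar x)^2,}
#' with row-normalized inverse-patristic weights, identifies tips sitting
#' in clades where the trait values cluster. Each tip's p-value comes from
#' a conditional permutation test -- the tip's own value is held fixed
#' while the other values are shuffled across the remaining tips -- and is
#' one-sided for positive local association. With row-normalized weights
#' the local values satisfy `sum(local_I) = n * global I`.
#'
#' @param tree A rooted `phylo`.
#' @param trait Named numeric trait over the tips.
#' @param n_permutations Permutations per tip (default 999).
#' @param seed Integer seed.
#' @param alpha Flagging level on the per-tip p-values (default 0.01).
#' @return A `lipa_result` with named vectors `local_I` and `p_value`,
#'   `flagged_tips` (p < alpha), and the run parameters.
#' @export
lipa <- function(tree, trait, n_permutations = 999, seed = 1L, alpha = 0.01) {
  n_permutations <- assert_scalar_count(n_permutations, "n_permutations",
                                        min = 99L)
  tree <- validate_tree(tree)
  x <- check_trait(trait, tree)
  if (stats::var(x) == 0) stop_fmt("trait has zero variance")
  W <- proximity_weights(tree, row_normalize = TRUE)
  n <- length(x)
  z <- x - mean(x)
  m2 <- sum(z^2) / n
  local_obs <- as.numeric((z / m2) * (W %*% z))
  names(local_obs) <- names(x)
  p <- with_seed(seed, {
    vapply(seq_len(n), function(i) {
      zi <- z[i]
      others <- z[-i]
      wi <- W[i, -i]
      perm_lag <- vapply(seq_len(n_permutations), function(b) {
        sum(wi * others[sample.int(n - 1)])
      }, numeric(1))
      perm_local <- (zi / m2) * perm_lag
      (1 + sum(perm_local >= local_obs[i])) / (1 + n_permutations)
    }, numeric(1))
  })
  names(p) <- names(x)
  structure(list(local_I = local_obs, p_value = p,
                 flagged_tips = names(p)[p < alpha],
                 n_permutations = n_permutations, seed = as.integer(seed),
                 alpha = alpha),
            class = "lipa_result")
}
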