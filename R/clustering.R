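#' Hierarchically cluster strains on a family subset
#'
#' Agglomerative clustering of strains restricted to the given family
#' columns, cut into `k` groups. Cluster labels are canonicalized by first
#' appearance in row order, so the result is deterministic and
#' permutation-equivariant.
#'
#' @param matrix A `trait_matrix` (strains x families counts).
#' @param family_ids Subset of matrix columns to cluster on (character),
#'   or a `family_set` object.
#' @param k Number of clusters (required; the dendrogram is cut, never
#'   auto-selected -- see [suggest_k()] for a silhouette-based suggestion).
#' @param distance Distance on count rows: `"euclidean"` (default) or
#'   `"manhattan"`.
#' @param linkage Agglomeration method passed to [stats::hclust()]:
#'   `"ward.D2"` (default), `"complete"`, `"average"` or `"single"`.
#' @return A `partition` object: list with `assignments` (named integer
#'   vector, labels 1..k) and `k`.
#' @export
hierarchical_partition <- function(matrix, family_ids = colnames(matrix), k,
                                   distance = c("euclidean", "manhattan"),
                                   linkage = c("ward.D2", "complete",
                                               "average", "single")) {
  distance <- match.arg(distance)
  linkage <- match.arg(linkage)
  if (inherits(family_ids, "family_set")) family_ids <- family_ids$family_ids
  k <- assert_scalar_count(k, "k")
  if (length(family_ids) == 0) stop_fmt("family_ids must be non-empty")
  missing <- setdiff(family_ids, colnames(matrix))
  if (length(missing) > 0) {
    stop_fmt("family id(s) not in matrix: %s", paste(missing, collapse = ", "))
  }
  if (k > nrow(matrix)) stop_fmt("k exceeds the number of strains")
  sub <- unclass(matrix)[, family_ids, drop = FALSE]
  if (k == 1L) {
    return(new_partition(stats::setNames(rep(1L, nrow(sub)), rownames(sub)), 1L))
  }
  d <- stats::dist(sub, method = distance)
  if (max(d) == 0) stop_fmt("degenerate distance matrix: all strains identical")
  hc <- stats::hclust(d, method = linkage)
  new_partition(stats::cutree(hc, k = k), k)
}

# Canonicalize labels by first appearance in row order.
new_partition <- function(assignments, k) {
  labs <- unique(unname(assignments))
  canon <- match(unname(assignments), labs)
  structure(list(assignments = stats::setNames(as.integer(canon),
                                               names(assignments)),
                 k = as.integer(k)),
            class = "partition")
}

#' Adjusted Rand index between two partitions of the same strains
#'
#' Chance-corrected agreement between two partitions; 1 exactly when the
#' partitions are identical up to relabeling, expectation 0 under random
#' labeling. Computed from the contingency table via the
#' Hubert-Arabie formula.
#'
#' @param p,q `partition` objects over identical strain sets (or bare named
#'   label vectors).
#' @return A single number in `[-1, 1]` (degenerate cases where both
#'   partitions are all-singletons or single-cluster return 1).
#' @export
adjusted_rand <- function(p, q) {
  pa <- if (inherits(p, "partition")) p$assignments else p
  qa <- if (inherits(q, "partition")) q$assignments else q
  if (is.null(names(pa)) || is.null(names(qa))) {
    stop_fmt("partitions must carry strain names")
  }
  if (!setequal(names(pa), names(qa)) || length(pa) != length(qa)) {
    stop_fmt("partitions are over different strain sets")
  }
  qa <- qa[names(pa)]
  n <- length(pa)
  tab <- table(pa, qa)
  choose2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(choose2(tab))
  sum_a <- sum(choose2(rowSums(tab)))
  sum_b <- sum(choose2(colSums(tab)))
  total <- choose2(n)
  expected <- sum_a * sum_b / total
  max_index <- (sum_a + sum_b) / 2
  if (max_index == expected) return(1)  # both trivial partitions
  (sum_ij - expected) / (max_index - expected)
}

#' Select the stable prevalence-threshold family set
#'
#' Clusters the strains once per nested family set and walks the sets from
#' the most restrictive (highest prevalence threshold) downward. The
#' selected set is the first whose partition agrees perfectly (adjusted
#' Rand index of 1) with the partitions of the next `m_consecutive`
#' lower-threshold sets -- the partition "plateau" indicating that adding
#' rarer families no longer changes the classification. Sets with fewer
#' than two families are skipped with a warning (their distance matrix is
#' degenerate for clustering purposes).
#'
#' @param matrix A `trait_matrix`.
#' @param sets A `family_set_list` from [build_family_sets()].
#' @param k Number of clusters to cut at (fixed across sets).
#' @param m_consecutive How many consecutive lower-threshold sets must agree
#'   (default 2, i.e. a threshold is accepted when the next two sweeps
#'   reproduce its clustering).
#' @param distance,linkage Passed to [hierarchical_partition()].
#' @return A `stability_result`: `selected_set_index`,
#'   `selected_threshold_percent`, `plateau_found`, per-set `partitions`
#'   (NULL where skipped), and `agreement`, the ARI between each
#'   consecutive pair of usable sets.
#' @export
select_stable_set <- function(matrix, sets, k, m_consecutive = 2,
                              distance = "euclidean", linkage = "ward.D2") {
  if (!inherits(sets, "family_set_list")) {
    stop_fmt("expected a 'family_set_list' (see build_family_sets)")
  }
  k <- assert_scalar_count(k, "k", min = 2L)
  m_consecutive <- assert_scalar_count(m_consecutive, "m_consecutive")
  n_sets <- length(sets)
  partitions <- vector("list", n_sets)
  usable <- logical(n_sets)
  for (i in seq_len(n_sets)) {
    ids <- sets[[i]]$family_ids
    if (length(ids) < 2) {
      warning(sprintf("skipping set %d (threshold %g%%): fewer than 2 families",
                      sets[[i]]$set_index, sets[[i]]$threshold_percent),
              call. = FALSE)
      next
    }
    part <- tryCatch(
      hierarchical_partition(matrix, ids, k = k,
                             distance = distance, linkage = linkage),
      error = function(e) {
        warning(sprintf("skipping set %d: %s", sets[[i]]$set_index,
                        conditionMessage(e)), call. = FALSE)
        NULL
      })
    partitions[[i]] <- part
    usable[i] <- !is.null(part)
  }
  if (!any(usable)) stop_fmt("no family set produced a usable clustering")
  agreement <- rep(NA_real_, n_sets - 1L)
  for (i in seq_len(n_sets - 1L)) {
    if (usable[i] && usable[i + 1L]) {
      agreement[i] <- adjusted_rand(partitions[[i]], partitions[[i + 1L]])
    }
  }
  tol <- 1e-12
  selected <- NA_integer_
  for (i in seq_len(n_sets - m_consecutive)) {
    idx <- i:(i + m_consecutive)
    if (!all(usable[idx])) next
    agree <- vapply(idx[-1], function(j) {
      adjusted_rand(partitions[[i]], partitions[[j]])
    }, numeric(1))
    if (all(agree >= 1 - tol)) {
      selected <- i
      break
    }
  }
  plateau_found <- !is.na(selected)
  if (!plateau_found) selected <- max(which(usable))
  structure(list(selected_set_index = sets[[selected]]$set_index,
                 selected_threshold_percent = sets[[selected]]$threshold_percent,
                 plateau_found = plateau_found,
                 k = k,
                 m_consecutive = m_consecutive,
                 partitions = partitions,
                 agreement = agreement),
            class = "stability_result")
}

#' Silhouette-based suggestion for the number of clusters
#'
#' Computes the mean silhouette width of [hierarchical_partition()] cuts
#' over a range of `k` and reports the maximizer. Purely advisory: nothing
#' in the pipeline ever applies it implicitly.
#'
#' @param matrix A `trait_matrix`.
#' @param family_ids Columns to cluster on (default all).
#' @param k_range Candidate values of `k` (default `2:8`).
#' @param distance,linkage Passed to [hierarchical_partition()].
#' @return A list with `best_k` and `mean_silhouette` (named by k).
#' @export
suggest_k <- function(matrix, family_ids = colnames(matrix), k_range = 2:8,
                      distance = "euclidean", linkage = "ward.D2") {
  if (inherits(family_ids, "family_set")) family_ids <- family_ids$family_ids
  d <- as.matrix(stats::dist(unclass(matrix)[, family_ids, drop = FALSE],
                             method = distance))
  widths <- vapply(k_range, function(k) {
    part <- hierarchical_partition(matrix, family_ids, k = k,
                                   distance = distance, linkage = linkage)
    mean_silhouette(d, part$assignments)
  }, numeric(1))
  names(widths) <- k_range
  list(best_k = k_range[which.max(widths)], mean_silhouette = widths)
}

mean_silhouette <- function(dmat, labels) {
  n <- length(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- labels == labels[i]
    a <- if (sum(own) > 1) sum(dmat[i, own]) / (sum(own) - 1) else NA_real_
    b <- min(vapply(setdiff(unique(labels), labels[i]), function(g) {
      mean(dmat[i, labels == g])
    }, numeric(1)))
    s[i] <- if (is.na(a)) 0 else (b - a) / max(a, b)
  }
  mean(s)
}
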