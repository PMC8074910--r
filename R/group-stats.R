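#' Kruskal-Wallis rank test across groups
#'
#' Tie-corrected Kruskal-Wallis H with an asymptotic chi-square p-value
#' (df = number of groups - 1). When every pooled value is identical the
#' tie-correction denominator vanishes; H is then defined as 0 with p = 1
#' and a warning.
#'
#' @param values_by_group A named list, one numeric vector per group
#'   (at least two non-empty groups, total N >= 3).
#' @return A list with `H`, `df` and `p_value`.
#' @export
kruskal_wallis <- function(values_by_group) {
  check_groups(values_by_group)
  g <- length(values_by_group)
  pooled <- unlist(values_by_group, use.names = FALSE)
  if (length(unique(pooled)) == 1L) {
    warning("all values identical across groups; H defined as 0", call. = FALSE)
    return(list(H = 0, df = g - 1L, p_value = 1))
  }
  groups <- factor(rep(names(values_by_group), lengths(values_by_group)),
                   levels = names(values_by_group))
  kt <- stats::kruskal.test(pooled, groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p_value = unname(kt$p.value))
}

check_groups <- function(values_by_group) {
  if (!is.list(values_by_group) || length(values_by_group) < 2) {
    stop_fmt("need a named list of at least 2 groups")
  }
  if (is.null(names(values_by_group)) || anyDuplicated(names(values_by_group))) {
    stop_fmt("group names must be unique and non-empty")
  }
  if (any(lengths(values_by_group) == 0)) stop_fmt("every group must be non-empty")
  if (sum(lengths(values_by_group)) < 3) stop_fmt("need at least 3 observations")
  invisible(TRUE)
}

#' Dunn's post hoc pairwise comparisons
#'
#' Pairwise z statistics on the pooled midranks with the usual tie
#' correction:
#' \deqn{z_{ab} = \frac{\bar R_a - \bar R_b}{\sqrt{\left[\frac{N(N+1)}{12} -
#'   \frac{\sum_t (t^3 - t)}{12(N-1)}\right]\left(\frac{1}{n_a} +
#'   \frac{1}{n_b}\right)}}}
#' with two-sided p-values from the standard normal, adjusted for the
#' number of pairwise comparisons.
#'
#' @param values_by_group As in [kruskal_wallis()].
#' @param adjustment Multiplicity adjustment across the pairwise
#'   comparisons: `"holm"` (default), `"BH"` or `"none"`.
#' @return A data frame with columns `group_a`, `group_b`, `z`, `p_value`
#'   and `p_adjusted`.
#' @export
dunn_posthoc <- function(values_by_group, adjustment = c("holm", "BH", "none")) {
  adjustment <- match.arg(adjustment)
  check_groups(values_by_group)
  gnames <- names(values_by_group)
  pooled <- unlist(values_by_group, use.names = FALSE)
  n_i <- lengths(values_by_group)
  N <- length(pooled)
  degenerate <- length(unique(pooled)) == 1L
  if (degenerate) {
    warning("all values identical across groups; Dunn z defined as 0",
            call. = FALSE)
  }
  r <- rank(pooled)  # midranks
  grp <- rep(seq_along(gnames), n_i)
  mean_rank <- tapply(r, grp, mean)
  ties <- table(pooled)
  tie_term <- sum(ties^3 - ties)
  var_base <- N * (N + 1) / 12 - tie_term / (12 * (N - 1))
  pairs <- utils::combn(length(gnames), 2)
  z <- vapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1, j]; b <- pairs[2, j]
    if (degenerate) return(0)
    (mean_rank[a] - mean_rank[b]) /
      sqrt(var_base * (1 / n_i[a] + 1 / n_i[b]))
  }, numeric(1))
  p <- if (degenerate) rep(1, length(z)) else 2 * stats::pnorm(-abs(z))
  data.frame(group_a = gnames[pairs[1, ]],
             group_b = gnames[pairs[2, ]],
             z = z,
             p_value = p,
             p_adjusted = stats::p.adjust(p, method = adjustment),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Scan features for association with dietary group
#'
#' Runs the Kruskal-Wallis test (and optionally Dunn's post hoc) for each
#' requested feature against the strains' dietary groups: per-family gene
#' counts, genome size, and/or GH content. Mirrors per-feature reporting:
#' no correction is applied across features by default (`feature_adjust`
#' offers BH).
#'
#' @param matrix A `trait_matrix`.
#' @param strains A `strain_metadata` table covering the matrix rows.
#' @param features Any of `"per_family"`, `"genome_size"`, `"gh_content"`.
#' @param alpha Significance level used for flagging (default 0.05).
#' @param posthoc Compute Dunn comparisons for each feature (default TRUE).
#' @param adjustment Dunn adjustment, see [dunn_posthoc()].
#' @param feature_adjust `"none"` (default) or `"BH"` across features.
#' @param group_by Metadata column defining the grouping (default
#'   `"diet_group"`; e.g. `"host_group"` for host-based scans).
#' @return A `group_scan_list`: per feature a `group_scan` with
#'   `feature_id`, `H`, `df`, `p_value`, `p_across_features`, `flagged`,
#'   `singleton_groups` (groups contributing a single strain) and
#'   `posthoc` (data frame or NULL).
#' @export
diet_association_scan <- function(matrix, strains,
                                  features = "per_family",
                                  alpha = 0.05,
                                  posthoc = TRUE,
                                  adjustment = "holm",
                                  feature_adjust = c("none", "BH"),
                                  group_by = "diet_group") {
  feature_adjust <- match.arg(feature_adjust)
  features <- match.arg(features,
                        c("per_family", "genome_size", "gh_content"),
                        several.ok = TRUE)
  strains <- as_strain_metadata(strains)
  idx <- match(rownames(matrix), strains$strain_id)
  if (anyNA(idx)) {
    stop_fmt("strain %s missing from metadata", rownames(matrix)[which(is.na(idx))[1]])
  }
  if (!group_by %in% names(strains)) {
    stop_fmt("metadata has no '%s' column", group_by)
  }
  grouping <- as.character(strains[[group_by]])[idx]
  groups <- unique(grouping)
  if (length(groups) < 2) stop_fmt("need at least 2 dietary groups, found %d",
                                   length(groups))
  singleton <- names(which(table(grouping) == 1))

  feature_values <- list()
  if ("per_family" %in% features) {
    for (f in colnames(matrix)) {
      feature_values[[f]] <- as.numeric(unclass(matrix)[, f])
    }
  }
  if ("genome_size" %in% features) {
    v <- strains$genome_size_bp[idx]
    if (is.null(v) || anyNA(v)) stop_fmt("genome_size_bp missing for some strains")
    feature_values[["genome_size"]] <- v
  }
  if ("gh_content" %in% features) {
    feature_values[["gh_content"]] <- gh_content(matrix, strains)$gh_percent
  }

  scans <- lapply(names(feature_values), function(fid) {
    vals <- split(feature_values[[fid]], grouping)
    kw <- suppressWarnings(kruskal_wallis(vals))
    ph <- if (posthoc) {
      suppressWarnings(dunn_posthoc(vals, adjustment = adjustment))
    } else NULL
    structure(list(feature_id = fid,
                   H = kw$H, df = kw$df, p_value = kw$p_value,
                   p_across_features = NA_real_,
                   flagged = kw$p_value < alpha,
                   singleton_groups = singleton,
                   posthoc = ph),
              class = "group_scan")
  })
  p_all <- vapply(scans, function(s) s$p_value, numeric(1))
  p_adj <- if (feature_adjust == "BH") stats::p.adjust(p_all, "BH") else p_all
  for (i in seq_along(scans)) scans[[i]]$p_across_features <- p_adj[i]
  structure(scans, class = c("group_scan_list", "list"))
}

#' Derive the characteristic-family table from a scan
#'
#' For each family whose Kruskal-Wallis p is below `alpha`, labels the
#' group with the top mean rank "high" (and the bottom one "low") provided
#' its Dunn-adjusted p-value beats `alpha` against more than a `majority`
#' fraction of the other groups -- a formalization of "significantly
#' high/low in this group versus the rest".
#'
#' @param scans A `group_scan_list` from [diet_association_scan()] run with
#'   `posthoc = TRUE`.
#' @param matrix,strains The matrix and metadata the scan was computed on.
#' @param alpha Significance level (default 0.05).
#' @param majority Fraction of other groups that must be beaten
#'   (strictly more than; default 0.5).
#' @param group_by Grouping column, matching the scan.
#' @return A `characteristic_table`: data frame `entries` with columns
#'   `group`, `family_id`, `direction` plus the `alpha` used.
#' @export
characteristic_families <- function(scans, matrix, strains, alpha = 0.05,
                                    majority = 0.5, group_by = "diet_group") {
  if (!inherits(scans, "group_scan_list")) stop_fmt("expected a 'group_scan_list'")
  strains <- as_strain_metadata(strains)
  idx <- match(rownames(matrix), strains$strain_id)
  grouping <- as.character(strains[[group_by]])[idx]
  entries <- list()
  for (scan in scans) {
    if (!scan$feature_id %in% colnames(matrix)) next
    if (is.na(scan$p_value) || scan$p_value >= alpha) next
    if (is.null(scan$posthoc)) {
      stop_fmt("scan for %s has no post hoc results; rerun with posthoc = TRUE",
               scan$feature_id)
    }
    vals <- as.numeric(unclass(matrix)[, scan$feature_id])
    mean_rank <- tapply(rank(vals), grouping, mean)
    ph <- scan$posthoc
    for (direction in c("high", "low")) {
      gstar <- names(mean_rank)[if (direction == "high") which.max(mean_rank)
                                else which.min(mean_rank)]
      others <- setdiff(names(mean_rank), gstar)
      wins <- vapply(others, function(o) {
        row <- ph[(ph$group_a == gstar & ph$group_b == o) |
                  (ph$group_a == o & ph$group_b == gstar), , drop = FALSE]
        nrow(row) == 1 && row$p_adjusted < alpha
      }, logical(1))
      if (mean(wins) > majority) {
        entries[[length(entries) + 1L]] <-
          data.frame(group = gstar, family_id = scan$feature_id,
                     direction = direction, stringsAsFactors = FALSE)
      }
    }
  }
  tab <- if (length(entries) > 0) {
    do.call(rbind, entries)
  } else {
    data.frame(group = character(0), family_id = character(0),
               direction = character(0), stringsAsFactors = FALSE)
  }
  structure(list(entries = tab, alpha = alpha), class = "characteristic_table")
}
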