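#' Build the strain x family gene-count matrix
#'
#' Pivots a long annotation table into a strain-by-family count matrix, the
#' central object of the pipeline. Missing (strain, family) pairs become
#' structural zeros; rows and columns are ordered lexicographically so the
#' matrix is deterministic regardless of input record order. Families never
#' observed (all-zero columns) are dropped with a notice.
#'
#' @param annotations An `annotation_table` (see [read_annotation_table()]).
#' @param strains A `strain_metadata` table covering the annotated strains.
#' @param drop_unknown_strains If `TRUE`, annotation records for strains
#'   absent from the metadata are dropped with a warning instead of being an
#'   error. Default `FALSE`: the two tables are expected to be curated
#'   jointly.
#' @return An integer matrix with strain ids as row names and family ids as
#'   column names, of class `trait_matrix`.
#' @export
build_matrix <- function(annotations, strains, drop_unknown_strains = FALSE) {
  annotations <- as_annotation_table(annotations)
  strains <- as_strain_metadata(strains)
  unknown <- setdiff(unique(annotations$strain_id), strains$strain_id)
  if (length(unknown) > 0) {
    if (!drop_unknown_strains) {
      stop_fmt("annotated strain(s) missing from metadata: %s%s",
               paste(utils::head(unknown, 5), collapse = ", "),
               if (length(unknown) > 5) ", ..." else "")
    }
    warning(sprintf("dropping %d strain(s) absent from metadata", length(unknown)),
            call. = FALSE)
    annotations <- annotations[!annotations$strain_id %in% unknown, , drop = FALSE]
  }
  if (nrow(annotations) == 0) {
    stop_fmt("no annotated strains remain after matching against metadata")
  }
  strain_ids <- sort(unique(annotations$strain_id))
  family_ids <- sort(unique(annotations$family_id))
  m <- matrix(0L, nrow = length(strain_ids), ncol = length(family_ids),
              dimnames = list(strain_ids, family_ids))
  m[cbind(match(annotations$strain_id, strain_ids),
          match(annotations$family_id, family_ids))] <- annotations$gene_count
  empty <- colSums(m) == 0L
  if (any(empty)) {
    message(sprintf("dropping %d family column(s) never observed (all zero)",
                    sum(empty)))
    m <- m[, !empty, drop = FALSE]
  }
  if (ncol(m) == 0) stop_fmt("no families with nonzero counts")
  class(m) <- c("trait_matrix", class(m))
  m
}

#' Per-family prevalence across strains
#'
#' Prevalence is presence-based: the fraction of strains carrying at least
#' one gene of the family, irrespective of copy number.
#'
#' @param matrix A `trait_matrix` (strains x families counts).
#' @return A named numeric vector in `[0, 1]`, one entry per family column.
#' @export
family_prevalence <- function(matrix) {
  if (nrow(matrix) == 0 || ncol(matrix) == 0) stop_fmt("empty trait matrix")
  colMeans(unclass(matrix) >= 1L)
}

# Thresholds of the 21 nested prevalence sets. Set 1 is the families shared
# by every strain (equality); set k >= 2 keeps families with prevalence
# strictly above (105 - 5k)%: >95%, >90%, ..., >20% (set 17), ..., >0% (set 21).
family_set_thresholds <- function() c(100, 105 - 5 * (2:21))

#' Build the 21 nested prevalence-threshold family sets
#'
#' Set 1 contains families present in 100% of strains (equality); set
#' \eqn{k \ge 2} contains families whose prevalence strictly exceeds
#' \eqn{(105 - 5k)\%} -- i.e. >95%, >90%, ..., down to >0%. Set 17 is the
#' ">20%" set. The sets are nested by construction.
#'
#' @param matrix A `trait_matrix`.
#' @return A list of 21 `family_set` objects (fields `set_index`,
#'   `threshold_percent`, `family_ids`), of class `family_set_list`.
#' @export
build_family_sets <- function(matrix) {
  prev <- family_prevalence(matrix)
  thresholds <- family_set_thresholds()
  sets <- lapply(seq_along(thresholds), function(i) {
    thr <- thresholds[i]
    ids <- if (i == 1L) {
      names(prev)[prev == 1]
    } else {
      names(prev)[prev > thr / 100]
    }
    structure(list(set_index = i,
                   threshold_percent = thr,
                   family_ids = ids),
              class = "family_set")
  })
  structure(sets, class = c("family_set_list", "list"))
}

#' Families shared by at least a given fraction of strains
#'
#' Convenience screen with an inclusive threshold (default >= 80% of
#' strains), distinct from the strict-inequality 21-set sweep of
#' [build_family_sets()].
#'
#' @param matrix A `trait_matrix`.
#' @param min_prevalence Inclusive prevalence cutoff in `[0, 1]` (default 0.8).
#' @return Character vector of family ids meeting the cutoff.
#' @export
prevalent_families <- function(matrix, min_prevalence = 0.8) {
  prev <- family_prevalence(matrix)
  names(prev)[prev >= min_prevalence]
}

#' Per-strain GH content
#'
#' GH content of a strain is the percentage of its coding sequences that
#' are GH genes: `100 * (row sum of the count matrix) / total_cds`.
#'
#' @param matrix A `trait_matrix`.
#' @param strains A `strain_metadata` table with `total_cds` for every
#'   strain in the matrix.
#' @return A data frame with columns `strain_id` and `gh_percent`, in the
#'   matrix row order.
#' @export
gh_content <- function(matrix, strains) {
  strains <- as_strain_metadata(strains)
  idx <- match(rownames(matrix), strains$strain_id)
  if (anyNA(idx)) {
    stop_fmt("strain %s missing from metadata", rownames(matrix)[which(is.na(idx))[1]])
  }
  cds <- strains$total_cds[idx]
  if (is.null(cds) || anyNA(cds)) {
    bad <- rownames(matrix)[if (is.null(cds)) 1L else which(is.na(cds))[1]]
    stop_fmt("total_cds missing for strain %s", bad)
  }
  data.frame(strain_id = rownames(matrix),
             gh_percent = 100 * rowSums(matrix) / cds,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' COG-class composition of the core genome across coverage levels
#'
#' For each coverage level `c`, the core is the set of gene clusters present
#' in at least `c`% of strains; the profile is the fraction of core clusters
#' in each COG class. Comparing these ratios across a sweep of levels (by
#' default 100% down to 83%) is how an appropriate core definition is chosen.
#'
#' @param pam A `presence_matrix_cog` (see [read_presence_matrix()]).
#' @param coverage_levels Numeric vector of percentages in (0, 100];
#'   default `100:83`.
#' @return A list of `cog_trend` objects, each with `coverage_percent`,
#'   `n_core` and a named `cog_ratios` vector summing to 1 (empty, with a
#'   warning, if no cluster reaches the level).
#' @export
cog_ratio_trend <- function(pam, coverage_levels = 100:83) {
  if (!inherits(pam, "presence_matrix_cog")) {
    stop_fmt("expected a 'presence_matrix_cog' object")
  }
  if (any(coverage_levels <= 0 | coverage_levels > 100)) {
    stop_fmt("coverage levels must lie in (0, 100]")
  }
  frac <- rowMeans(pam$presence)
  lapply(coverage_levels, function(level) {
    core <- frac >= level / 100
    if (!any(core)) {
      warning(sprintf("no core clusters at coverage level %g%%", level),
              call. = FALSE)
      ratios <- stats::setNames(numeric(0), character(0))
    } else {
      tab <- table(pam$cog_class[core])
      ratios <- as.numeric(tab) / sum(tab)
      names(ratios) <- names(tab)
    }
    structure(list(coverage_percent = level,
                   n_core = sum(core),
                   cog_ratios = ratios),
              class = "cog_trend")
  })
}
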