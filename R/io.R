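#' Read a per-strain gene-family annotation table
#'
#' Reads a tab-separated table with columns `strain_id`, `family_id` and
#' `gene_count` -- the shape of a summarized CAZyme annotation (one row per
#' strain/family pair, giving the number of genes of that family found in
#' that genome).
#'
#' @param path Path to a UTF-8, tab-separated file with a header row.
#' @return A `data.frame` of class `annotation_table` with columns
#'   `strain_id` (character), `family_id` (character) and `gene_count`
#'   (non-negative integer).
#' @details Validation is strict: duplicated (strain, family) pairs and
#'   negative counts are rejected with the offending data row named.
#' @export
read_annotation_table <- function(path) {
  df <- read_tsv_checked(path, c("strain_id", "family_id", "gene_count"),
                         "annotation table")
  as_annotation_table(df)
}

#' Validate an in-memory annotation table
#'
#' @param df A data frame with columns `strain_id`, `family_id`, `gene_count`.
#' @return The validated `annotation_table`.
#' @export
as_annotation_table <- function(df) {
  required <- c("strain_id", "family_id", "gene_count")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("annotation table is missing required column(s): %s",
             paste(missing, collapse = ", "))
  }
  if (nrow(df) == 0) stop_fmt("annotation table has no records")
  df$strain_id <- as.character(df$strain_id)
  df$family_id <- as.character(df$family_id)
  cnt <- suppressWarnings(as.numeric(df$gene_count))
  bad <- which(is.na(cnt) | cnt < 0 | cnt != round(cnt))
  if (length(bad) > 0) {
    stop_fmt("invalid gene_count at data row %d (value '%s'): must be an integer >= 0",
             bad[1], as.character(df$gene_count[bad[1]]))
  }
  df$gene_count <- as.integer(cnt)
  key <- paste(df$strain_id, df$family_id, sep = "\r")
  dup <- which(duplicated(key))
  if (length(dup) > 0) {
    stop_fmt("duplicated (strain_id, family_id) pair at data row %d: (%s, %s)",
             dup[1], df$strain_id[dup[1]], df$family_id[dup[1]])
  }
  df <- df[, required]
  class(df) <- c("annotation_table", "data.frame")
  df
}

#' Read a strain metadata table
#'
#' Reads a tab-separated table with one row per strain. `strain_id` and
#' `diet_group` are required; `host_group`, `genome_size_bp`, `gc_percent`
#' and `total_cds` are recognized optional columns (empty or "." = missing).
#' Any further columns are carried along untouched.
#'
#' @param path Path to a tab-separated file with a header row.
#' @return A `data.frame` of class `strain_metadata`, one row per strain.
#' @export
read_metadata <- function(path) {
  df <- read_tsv_checked(path, c("strain_id", "diet_group"), "metadata table")
  as_strain_metadata(df)
}

#' Validate an in-memory strain metadata table
#'
#' @param df A data frame with at least `strain_id` and `diet_group` columns.
#' @return The validated `strain_metadata`.
#' @export
as_strain_metadata <- function(df) {
  for (col in c("strain_id", "diet_group")) {
    if (!col %in% names(df)) {
      stop_fmt("metadata table is missing required column(s): %s", col)
    }
  }
  if (nrow(df) == 0) stop_fmt("metadata table has no records")
  df$strain_id <- as.character(df$strain_id)
  df$diet_group <- as.character(df$diet_group)
  dup <- which(duplicated(df$strain_id))
  if (length(dup) > 0) {
    stop_fmt("duplicated strain_id in metadata: %s", df$strain_id[dup[1]])
  }
  empty <- which(is.na(df$diet_group) | !nzchar(trimws(df$diet_group)))
  if (length(empty) > 0) {
    stop_fmt("empty diet_group for strain %s", df$strain_id[empty[1]])
  }
  if ("genome_size_bp" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$genome_size_bp))
    bad <- which(!is.na(df$genome_size_bp) & (is.na(v) | v <= 0))
    if (length(bad) > 0) {
      stop_fmt("genome_size_bp must be > 0 (strain %s)", df$strain_id[bad[1]])
    }
    df$genome_size_bp <- v
  }
  if ("gc_percent" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$gc_percent))
    bad <- which(!is.na(df$gc_percent) & (is.na(v) | v <= 0 | v >= 100))
    if (length(bad) > 0) {
      stop_fmt("gc_percent must lie in (0, 100) (strain %s)", df$strain_id[bad[1]])
    }
    df$gc_percent <- v
  }
  if ("total_cds" %in% names(df)) {
    v <- suppressWarnings(as.numeric(df$total_cds))
    bad <- which(!is.na(df$total_cds) & (is.na(v) | v <= 0 | v != round(v)))
    if (length(bad) > 0) {
      stop_fmt("total_cds must be a positive integer (strain %s)", df$strain_id[bad[1]])
    }
    df$total_cds <- as.integer(v)
  }
  class(df) <- c("strain_metadata", "data.frame")
  df
}

#' Read a rooted phylogeny with branch lengths from a Newick file
#'
#' @param path Path to a file holding one Newick string.
#' @param default_branch_length Optional non-negative number substituted for
#'   missing branch lengths; by default missing lengths are an error.
#' @return An [ape::read.tree()] `phylo` object, rooted, with all branch
#'   lengths present and non-negative and unique tip labels.
#' @export
read_newick <- function(path, default_branch_length = NULL) {
  if (!file.exists(path)) stop_fmt("Newick file not found: %s", path)
  tree <- ape::read.tree(path)
  if (is.null(tree)) stop_fmt("could not parse a Newick tree from %s", path)
  if (inherits(tree, "multiPhylo")) tree <- tree[[1]]
  validate_tree(tree, default_branch_length = default_branch_length)
}

#' Validate a phylogeny for use in the pipeline
#'
#' @param tree A `phylo` object.
#' @param default_branch_length Optional substitute for missing lengths.
#' @param min_tips Minimum number of tips required (default 3).
#' @return The validated tree.
#' @export
validate_tree <- function(tree, default_branch_length = NULL, min_tips = 3L) {
  if (!inherits(tree, "phylo")) stop_fmt("expected a 'phylo' tree object")
  if (ape::Ntip(tree) < min_tips) {
    stop_fmt("tree must have at least %d tips", min_tips)
  }
  dup <- which(duplicated(tree$tip.label))
  if (length(dup) > 0) {
    stop_fmt("duplicate tip label in tree: %s", tree$tip.label[dup[1]])
  }
  if (is.null(tree$edge.length) || anyNA(tree$edge.length)) {
    if (is.null(default_branch_length)) {
      stop_fmt("branch lengths required (none or incomplete in input)")
    }
    if (default_branch_length < 0) stop_fmt("default branch length must be >= 0")
    if (is.null(tree$edge.length)) {
      tree$edge.length <- rep(default_branch_length, nrow(tree$edge))
    } else {
      tree$edge.length[is.na(tree$edge.length)] <- default_branch_length
    }
  }
  if (any(tree$edge.length < 0)) stop_fmt("negative branch length in tree")
  # The basal node of the parsed Newick string is taken as the root. Trees
  # with a basal polytomy (star phylogenies included) are valid here even
  # though ape's binary-root convention would call them unrooted.
  tree
}

#' Read a pan-genome presence/absence matrix with COG class labels
#'
#' The expected layout is tab-separated with columns `cluster_id`,
#' `cog_class`, then one 0/1 column per strain. Clusters with no functional
#' assignment should carry the label `"unassigned"`.
#'
#' @param path Path to the tab-separated file.
#' @return A list of class `presence_matrix_cog` with elements
#'   `cluster_id` (character), `cog_class` (character) and `presence`
#'   (clusters x strains 0/1 integer matrix).
#' @export
read_presence_matrix <- function(path) {
  df <- read_tsv_checked(path, c("cluster_id", "cog_class"),
                         "presence/absence matrix")
  strain_cols <- setdiff(names(df), c("cluster_id", "cog_class"))
  if (length(strain_cols) == 0) stop_fmt("presence/absence matrix has no strain columns")
  pres <- as.matrix(df[, strain_cols, drop = FALSE])
  storage.mode(pres) <- "integer"
  if (anyNA(pres) || !all(pres %in% c(0L, 1L))) {
    stop_fmt("presence values must all be 0 or 1")
  }
  rownames(pres) <- df$cluster_id
  as_presence_matrix(df$cluster_id, as.character(df$cog_class), pres)
}

#' Construct a validated presence/absence object
#'
#' @param cluster_id Character vector of unique cluster identifiers.
#' @param cog_class Character vector of single-letter COG categories (or
#'   `"unassigned"`), one per cluster.
#' @param presence Clusters x strains 0/1 matrix.
#' @return A `presence_matrix_cog` list.
#' @export
as_presence_matrix <- function(cluster_id, cog_class, presence) {
  cluster_id <- as.character(cluster_id)
  if (anyDuplicated(cluster_id)) stop_fmt("cluster_id values must be unique")
  if (length(cog_class) != length(cluster_id) ||
      nrow(presence) != length(cluster_id)) {
    stop_fmt("cluster_id, cog_class and presence rows must align")
  }
  structure(list(cluster_id = cluster_id,
                 cog_class = as.character(cog_class),
                 presence = presence),
            class = "presence_matrix_cog")
}

# ---- results serialization ------------------------------------------------
# Every pipeline result type serializes to a self-describing JSON document
# (field "result_type" + a fixed schema per type) so downstream checks are
# machine-readable; read_results() reconstructs the original object.

serializable_types <- c("signal_result", "partition", "stability_result",
                        "group_scan_list", "lipa_result",
                        "correlogram_result", "family_set_list",
                        "characteristic_table")

#' Write a pipeline result to a self-describing JSON document
#'
#' @param results A result object produced by this package (a `partition`,
#'   `signal_result`, `stability_result`, `lipa_result`,
#'   `correlogram_result`, list of family sets, list of group scans, or a
#'   characteristic-family table).
#' @param path Output file path.
#' @return Invisibly, the path written.
#' @seealso [read_results()]
#' @export
write_results <- function(results, path) {
  type <- intersect(class(results), serializable_types)[1]
  if (is.na(type)) {
    stop_fmt("don't know how to serialize an object of class '%s'",
             paste(class(results), collapse = "/"))
  }
  doc <- list(result_type = type,
              package = "glycodiet",
              version = as.character(utils::packageVersion("glycodiet")),
              payload = unclass_deep(results))
  ok <- tryCatch({
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", na = "null")
    TRUE
  }, error = function(e) {
    stop_fmt("could not write results to %s: %s", path, conditionMessage(e))
  })
  invisible(path)
}

unclass_deep <- function(x) {
  if (is.matrix(x)) {
    return(list(.matrix = TRUE, rownames = rownames(x), colnames = colnames(x),
                data = apply(unname(x), 1, function(r) unname(r), simplify = FALSE)))
  }
  if (is.data.frame(x)) {
    return(list(.data_frame = TRUE,
                columns = lapply(as.list(x), function(col) unname(col)),
                names = names(x)))
  }
  if (is.list(x)) {
    x <- unclass(x)
    return(lapply(x, unclass_deep))
  }
  # jsonlite drops names on atomic vectors; keep them via a list (object)
  if (is.atomic(x) && !is.null(names(x))) return(as.list(x))
  x
}

reclass_deep <- function(x) {
  if (is.list(x) && isTRUE(x$.matrix)) {
    m <- do.call(rbind, lapply(x$data, function(r) unlist(r)))
    if (is.null(m)) m <- matrix(numeric(0), 0, 0)
    rownames(m) <- unlist(x$rownames)
    colnames(m) <- unlist(x$colnames)
    return(m)
  }
  if (is.list(x) && isTRUE(x$.data_frame)) {
    cols <- lapply(x$columns, function(col) {
      # JSON null (from NA) comes back as NULL; unlist() would drop it
      col[vapply(col, is.null, logical(1))] <- NA
      unlist(col)
    })
    df <- as.data.frame(cols, stringsAsFactors = FALSE, check.names = FALSE)
    names(df) <- unlist(x$names)
    return(df)
  }
  if (is.list(x)) return(lapply(x, reclass_deep))
  x
}

#' Read back a result document written by [write_results()]
#'
#' @param path Path to the JSON document.
#' @return The reconstructed result object, carrying its original class.
#' @export
read_results <- function(path) {
  if (!file.exists(path)) stop_fmt("results file not found: %s", path)
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  type <- doc$result_type
  if (is.null(type) || !type %in% serializable_types) {
    stop_fmt("not a recognized results document: %s", path)
  }
  payload <- reclass_deep(doc$payload)
  restore_result(payload, type)
}

restore_result <- function(payload, type) {
  out <- switch(type,
    signal_result = {
      payload$K <- as.numeric(payload$K)
      payload$p_value <- as.numeric(payload$p_value)
      payload$n_permutations <- as.integer(payload$n_permutations)
      payload$seed <- as.integer(payload$seed)
      payload$K_permuted <- as.numeric(unlist(payload$K_permuted))
      payload
    },
    partition = {
      asg <- unlist(payload$assignments)
      payload$assignments <- stats::setNames(as.integer(asg), names(asg))
      payload$k <- as.integer(payload$k)
      payload
    },
    stability_result = {
      payload$partitions <- lapply(payload$partitions, function(p) {
        if (is.null(p)) return(NULL)
        structure(restore_result(p, "partition"), class = "partition")
      })
      payload$agreement <- as.numeric(unlist(payload$agreement))
      payload$selected_set_index <- as.integer(payload$selected_set_index)
      payload$selected_threshold_percent <-
        as.numeric(payload$selected_threshold_percent)
      payload$plateau_found <- isTRUE(payload$plateau_found)
      payload
    },
    group_scan_list = {
      payload <- lapply(payload, function(s) {
        s$H <- as.numeric(s$H); s$df <- as.integer(s$df)
        s$p_value <- as.numeric(s$p_value)
        structure(s, class = "group_scan")
      })
      payload
    },
    lipa_result = {
      li <- unlist(payload$local_I)
      payload$local_I <- stats::setNames(as.numeric(li), names(li))
      pv <- unlist(payload$p_value)
      payload$p_value <- stats::setNames(as.numeric(pv), names(pv))
      payload$flagged_tips <- as.character(unlist(payload$flagged_tips))
      payload$alpha <- as.numeric(payload$alpha)
      payload
    },
    correlogram_result = payload,
    family_set_list = {
      payload <- lapply(payload, function(s) {
        s$set_index <- as.integer(s$set_index)
        s$threshold_percent <- as.numeric(s$threshold_percent)
        s$family_ids <- as.character(unlist(s$family_ids))
        structure(s, class = "family_set")
      })
      payload
    },
    characteristic_table = payload,
    stop_fmt("unknown result type '%s'", type))
  if (type %in% c("group_scan_list", "family_set_list")) {
    class(out) <- c(type, "list")
  } else {
    class(out) <- type
  }
  out
}
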