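#' glycodiet: GH gene repertoires versus host diet
#'
#' Comparative-genomics pipeline linking glycoside-hydrolase family
#' repertoires to host diet: trait matrices and prevalence-threshold family
#' sets, clustering-stability selection, dietary-group rank statistics, and
#' phylogenetic-signal estimation, plus a seeded synthetic-data generator.
#'
#' @keywords internal
"_PACKAGE"

# Run code with a temporarily seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
          rm(".Random.seed", envir = globalenv())
        }
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    })
    set.seed(seed)
  }
  force(code)
}

stop_fmt <- function(...) stop(sprintf(...), call. = FALSE)

assert_scalar_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop_fmt("'%s' must be a single integer >= %d", name, min)
  }
  as.integer(x)
}

read_tsv_checked <- function(path, required, what) {
  if (!file.exists(path)) stop_fmt("%s file not found: %s", what, path)
  df <- utils::read.delim(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, check.names = FALSE,
                          na.strings = c("NA", "."), quote = "",
                          comment.char = "")
  missing <- setdiff(required, names(df))
  if (length(missing) > 0) {
    stop_fmt("%s is missing required column(s): %s", what,
             paste(missing, collapse = ", "))
  }
  df
}
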