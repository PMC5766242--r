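#' @importFrom rlang abort warn %||%
#' @importFrom stats sd quantile setNames prcomp t.test dist hclust kmeans
#'   p.adjust cor rnbinom runif
#' @importFrom utils head
NULL

# Derive a child seed for an independent RNG stream. Keeps results reproducible
# from one user-facing seed while decoupling, e.g., permutation draws from
# random gene-set draws. Stays well below 2^31.
stream_seed <- function(seed, stream) {
  base <- as.numeric(seed) %% 1e6
  as.integer(base * 1511 + 7 * stream + 13) %% 2147483647L
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv())) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv())) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

# shared input checks ---------------------------------------------------------

check_matrix <- function(x, what = "matrix") {
  if (!is.matrix(x) || is.null(rownames(x)) || is.null(colnames(x))) {
    abort(sprintf("`%s` must be a matrix with row and column names", what))
  }
  invisible(x)
}

check_annotation <- function(annotation) {
  req <- c("sample_id", "tissue", "condition")
  missing <- setdiff(req, names(annotation))
  if (length(missing) > 0) {
    abort(paste0("annotation is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  if (anyDuplicated(annotation$sample_id)) {
    abort("annotation sample_id values must be unique")
  }
  bad <- setdiff(unique(annotation$condition), c("tumor", "normal"))
  if (length(bad) > 0) {
    abort(paste0("condition must be 'tumor' or 'normal'; found: ",
                 paste(bad, collapse = ", ")))
  }
  invisible(annotation)
}
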