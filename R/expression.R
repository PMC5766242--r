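#' Read a count matrix and its sample annotation
#'
#' Loads a genes-by-samples raw count matrix (TSV, first column `entrez_id`,
#' one column per sample) together with a sample annotation table
#' (`sample_id`, `tissue`, `condition` with condition one of
#' `tumor`/`normal`). Samples are aligned to the annotation order and genes
#' sorted by Entrez id. Gzip-compressed files are read transparently.
#'
#' @param matrix_path Path to the count TSV.
#' @param annotation_path Path to the annotation TSV.
#' @return A list with elements `counts` (integer matrix, rownames = Entrez
#'   ids) and `annotation` (tibble).
#' @export
read_counts <- function(matrix_path, annotation_path) {
  raw <- readr::read_tsv(matrix_path, show_col_types = FALSE)
  if (!"entrez_id" %in% names(raw)) {
    abort("count matrix must have an `entrez_id` first column")
  }
  annotation <- readr::read_tsv(annotation_path, show_col_types = FALSE)
  check_annotation(annotation)
  sample_cols <- setdiff(names(raw), "entrez_id")
  missing <- setdiff(sample_cols, annotation$sample_id)
  if (length(missing) > 0) {
    abort(paste0("sample(s) in matrix absent from annotation: ",
                 paste(missing, collapse = ", ")))
  }
  counts <- as.matrix(raw[, annotation$sample_id, drop = FALSE])
  if (any(counts != round(counts)) || any(counts < 0)) {
    abort("counts must be non-negative integers")
  }
  storage.mode(counts) <- "integer"
  rownames(counts) <- as.character(raw$entrez_id)
  ord <- order(as.integer(rownames(counts)))
  counts <- counts[ord, , drop = FALSE]
  list(counts = counts, annotation = tibble::as_tibble(annotation))
}

#' Write a count matrix alongside its annotation
#'
#' Inverse of [read_counts()]; used by the simulators and the pipeline.
#'
#' @param counts Integer matrix with Entrez-id rownames.
#' @param annotation Sample annotation tibble.
#' @param matrix_path,annotation_path Output paths.
#' @return `matrix_path`, invisibly.
#' @export
write_counts <- function(counts, annotation, matrix_path, annotation_path) {
  check_matrix(counts, "counts")
  out <- tibble::tibble(entrez_id = as.integer(rownames(counts)))
  out <- dplyr::bind_cols(out, tibble::as_tibble(counts))
  readr::write_tsv(out, matrix_path)
  readr::write_tsv(annotation, annotation_path)
  invisible(matrix_path)
}

#' Transform counts to log2 counts per million
#'
#' Applies the voom-convention logCPM transform
#' `log2((count + 0.5) / (libsize + 1) * 1e6)`, with library size the column
#' sum of the count matrix. Precision weights are not estimated; only the
#' transformed matrix is used downstream.
#'
#' @param counts Non-negative integer matrix (genes x samples).
#' @param lib_size Optional per-sample library sizes; defaults to column sums.
#' @return A numeric matrix of logCPM values with attribute `centered = FALSE`.
#' @export
#' @examples
#' m <- matrix(c(100L, 0L), 1, 2, dimnames = list("1", c("a", "b")))
#' log_cpm(m)
log_cpm <- function(counts, lib_size = NULL) {
  check_matrix(counts, "counts")
  if (any(counts < 0)) abort("counts must be non-negative")
  lib_size <- lib_size %||% colSums(counts)
  if (any(lib_size <= 0)) {
    abort(paste0("empty sample column(s): ",
                 paste(colnames(counts)[lib_size <= 0], collapse = ", ")))
  }
  expr <- log2(sweep(counts + 0.5, 2, lib_size + 1, "/") * 1e6)
  attr(expr, "centered") <- FALSE
  expr
}

#' Center expression gene-wise
#'
#' Subtracts the per-gene mean, either within each tissue (the default scope:
#' each cohort is normalised internally, matching how the gene-set and
#' Meta-PCA steps operate tissue-wise) or across all samples.
#'
#' @param expr Numeric matrix (genes x samples).
#' @param annotation Sample annotation; required for `scope = "per-tissue"`.
#' @param scope `"per-tissue"` or `"global"`.
#' @return The centered matrix, attribute `centered = TRUE` and
#'   `centering_scope` recording the scope.
#' @export
center_genes <- function(expr, annotation = NULL,
                         scope = c("per-tissue", "global")) {
  scope <- match.arg(scope)
  check_matrix(expr, "expr")
  if (scope == "global") {
    out <- expr - rowMeans(expr)
  } else {
    if (is.null(annotation)) abort("per-tissue centering needs `annotation`")
    check_annotation(annotation)
    ann <- annotation[match(colnames(expr), annotation$sample_id), ]
    if (anyNA(ann$sample_id)) {
      abort("all expression samples must appear in the annotation")
    }
    out <- expr
    for (ti in unique(ann$tissue)) {
      idx <- which(ann$tissue == ti)
      if (length(idx) == 1) {
        warn(sprintf("tissue '%s' has a single sample; values centered to 0", ti))
      }
      out[, idx] <- expr[, idx, drop = FALSE] -
        rowMeans(expr[, idx, drop = FALSE])
    }
  }
  attr(out, "centered") <- TRUE
  attr(out, "centering_scope") <- scope
  out
}

#' Tissues with both tumor and normal samples
#'
#' Filters tissue cohorts to those providing both arms, with a configurable
#' minimum number of samples per arm.
#'
#' @param annotation Sample annotation tibble.
#' @param min_per_arm Minimum samples required in each arm (default 1).
#' @return Character vector of retained tissue labels.
#' @export
select_paired_tissues <- function(annotation, min_per_arm = 1) {
  check_annotation(annotation)
  counts <- dplyr::count(annotation, .data$tissue, .data$condition)
  wide <- tidyr::pivot_wider(counts, names_from = "condition",
                             values_from = "n", values_fill = 0L)
  if (!"tumor" %in% names(wide)) wide$tumor <- 0L
  if (!"normal" %in% names(wide)) wide$normal <- 0L
  keep <- wide$tissue[wide$tumor >= min_per_arm & wide$normal >= min_per_arm]
  as.character(sort(keep))
}
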