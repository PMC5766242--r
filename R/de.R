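#' Per-gene differential expression, tumor versus normal
#'
#' Two-group linear model per gene. With `moderation = "on"` the gene-wise
#' variance is shrunk towards a common prior by empirical Bayes (limma's
#' moderated t); with `moderation = "off"` an ordinary pooled-variance t test
#' is used, which doubles as a dependency-light oracle for the moderated
#' path. Genes with zero variance in both arms get statistic 0 and p = 1.
#'
#' @param expr logCPM matrix (genes x samples) for one tissue.
#' @param condition Per-sample labels (`tumor`/`normal`).
#' @param moderation `"on"` (empirical-Bayes shrinkage) or `"off"`.
#' @return Tibble `gene_id`, `effect` (tumor - normal mean logCPM),
#'   `statistic`, `p_value`, `p_adjusted` (Benjamini-Hochberg).
#' @export
de_test <- function(expr, condition, moderation = c("on", "off")) {
  moderation <- match.arg(moderation)
  check_matrix(expr, "expr")
  condition <- as.character(condition)
  i1 <- which(condition == "tumor")
  i2 <- which(condition == "normal")
  if (length(i1) < 2 || length(i2) < 2) {
    abort("de_test needs at least 2 samples per arm")
  }
  if (moderation == "on") {
    design <- cbind(Intercept = 1, tumor = as.numeric(condition == "tumor"))
    fit <- limma::eBayes(limma::lmFit(expr, design))
    effect <- fit$coefficients[, "tumor"]
    statistic <- fit$t[, "tumor"]
    p <- fit$p.value[, "tumor"]
    bad <- !is.finite(statistic)
    statistic[bad] <- 0
    p[bad] <- 1
  } else {
    scores <- score_engine(expr, i1, i2, var_equal = TRUE)
    effect <- rowMeans(expr[, i1, drop = FALSE]) -
      rowMeans(expr[, i2, drop = FALSE])
    statistic <- as.numeric(scores)
    df <- length(i1) + length(i2) - 2
    p <- 2 * stats::pt(-abs(statistic), df = df)
    p[statistic == 0 & effect == 0] <- 1
  }
  tibble::tibble(gene_id = rownames(expr), effect = unname(effect),
                 statistic = unname(statistic), p_value = unname(p),
                 p_adjusted = bh_adjust(unname(p)))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment with monotonicity enforcement;
#' order-preserving in the input.
#'
#' @param pvalues Numeric vector in `[0, 1]`.
#' @return Adjusted p values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  stats::p.adjust(pvalues, method = "BH")
}

#' Fraction of differentially expressed genes in a set
#'
#' The share of set genes whose adjusted p value falls below `alpha`, the
#' per-subset summary behind the box plots of functional-subset deregulation.
#'
#' @param de_result Tibble from [de_test()].
#' @param gene_set Gene ids; all must have been tested.
#' @param alpha Adjusted-p threshold (default 0.05).
#' @return Length-1 numeric fraction in `[0, 1]`.
#' @export
de_fraction <- function(de_result, gene_set, alpha = 0.05) {
  if (length(gene_set) == 0) abort("empty gene set")
  idx <- match(as.character(gene_set), de_result$gene_id)
  if (anyNA(idx)) {
    abort(paste0("untested gene(s) in set: ",
                 paste(gene_set[is.na(idx)], collapse = ", ")))
  }
  mean(de_result$p_adjusted[idx] < alpha)
}

#' Gene-level signed significance
#'
#' `sign(effect) * (1 - p)` from the per-gene pooled t test, in `[-1, +1]`:
#' values near +1 flag strong upregulation in tumors, near -1 strong
#' downregulation. Genes with no expression difference score 0.
#'
#' @param expr logCPM matrix (genes x samples) for one tissue.
#' @param condition Per-sample labels (`tumor`/`normal`).
#' @param genes Gene ids to report; default all rows.
#' @return Tibble `gene_id`, `effect`, `p_value`, `signed_significance`.
#' @export
signed_significance <- function(expr, condition, genes = NULL) {
  de <- de_test(expr, condition, moderation = "off")
  if (!is.null(genes)) {
    idx <- match(as.character(genes), de$gene_id)
    if (anyNA(idx)) {
      abort(paste0("gene(s) absent from expr: ",
                   paste(genes[is.na(idx)], collapse = ", ")))
    }
    de <- de[idx, ]
  }
  sign_eff <- sign(de$effect)
  tibble::tibble(gene_id = de$gene_id, effect = de$effect,
                 p_value = de$p_value,
                 signed_significance = sign_eff * (1 - de$p_value))
}
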