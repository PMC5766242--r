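#' Per-gene two-sample scores for one tissue
#'
#' Computes the per-gene two-sample t statistic between tumor and normal
#' samples; a positive score means the tumor mean exceeds the normal mean.
#' The default is the pooled-variance (Student) statistic; `var_equal = FALSE`
#' switches to the Welch form. Genes with zero variance in both arms score 0
#' (with a warning).
#'
#' @param expr Numeric matrix (genes x samples).
#' @param condition Character/factor per sample, values `tumor`/`normal`.
#' @param var_equal Pooled-variance statistic (default) or Welch.
#' @return Named numeric vector of gene scores.
#' @export
gene_scores <- function(expr, condition, var_equal = TRUE) {
  check_matrix(expr, "expr")
  condition <- as.character(condition)
  i1 <- which(condition == "tumor")
  i2 <- which(condition == "normal")
  if (length(i1) < 2 || length(i2) < 2) {
    abort("gene_scores needs at least 2 samples per condition")
  }
  scores <- score_engine(expr, i1, i2, var_equal)
  n_zero <- attr(scores, "n_zero_variance")
  if (n_zero > 0) {
    warn(sprintf("%d gene(s) with zero variance in both groups scored 0", n_zero))
  }
  attr(scores, "n_zero_variance") <- NULL
  scores
}

# Vectorised scoring core shared with the permutation loop (no warnings there).
score_engine <- function(expr, i1, i2, var_equal) {
  n1 <- length(i1)
  n2 <- length(i2)
  x1 <- expr[, i1, drop = FALSE]
  x2 <- expr[, i2, drop = FALSE]
  m1 <- rowMeans(x1)
  m2 <- rowMeans(x2)
  v1 <- rowSums((x1 - m1)^2) / (n1 - 1)
  v2 <- rowSums((x2 - m2)^2) / (n2 - 1)
  if (var_equal) {
    vp <- ((n1 - 1) * v1 + (n2 - 1) * v2) / (n1 + n2 - 2)
    se <- sqrt(vp * (1 / n1 + 1 / n2))
  } else {
    se <- sqrt(v1 / n1 + v2 / n2)
  }
  t <- (m1 - m2) / se
  zero <- se == 0 | !is.finite(t)
  t[zero] <- 0
  structure(setNames(t, rownames(expr)), n_zero_variance = sum(se == 0))
}

#' The maxmean gene-set statistic
#'
#' The mean of the positive or the negative gene scores in the set, whichever
#' is larger in absolute value. Ties (`s+ == |s-|`) return the positive value.
#'
#' @param scores Named numeric vector of gene scores.
#' @param set Gene ids (matching `names(scores)`) or integer indices.
#' @return The maxmean statistic, a length-1 numeric.
#' @export
#' @examples
#' maxmean(c(a = 2, b = -1, c = 3, d = -1), c("a", "b", "c", "d")) # 1.25
maxmean <- function(scores, set) {
  if (length(set) == 0) abort("empty gene set")
  s <- if (is.numeric(set)) scores[set] else scores[as.character(set)]
  if (anyNA(s)) {
    abort("set contains genes without scores")
  }
  m <- length(s)
  s_pos <- sum(pmax(s, 0)) / m
  s_neg <- sum(pmin(s, 0)) / m
  if (s_pos >= abs(s_neg)) s_pos else s_neg
}

# maxmean over a score vector and an index set, no checks (hot loop).
maxmean_fast <- function(s) {
  m <- length(s)
  s_pos <- sum(pmax(s, 0)) / m
  s_neg <- sum(pmin(s, 0)) / m
  if (s_pos >= abs(s_neg)) s_pos else s_neg
}

#' Signed gene-set score from up/down p values
#'
#' `delta_gsa = (1 - p_up) - (1 - p_down) = p_down - p_up`, in `[-1, +1]`:
#' +1 flags significant upregulation, -1 significant downregulation.
#'
#' @param p_up,p_down Numeric vectors in `[0, 1]`.
#' @return Numeric vector of signed scores.
#' @export
delta_gsa <- function(p_up, p_down) {
  if (any(p_up < 0 | p_up > 1 | p_down < 0 | p_down > 1, na.rm = TRUE)) {
    abort("p values must lie in [0, 1]")
  }
  p_down - p_up
}

# Permutation scaffold for one tissue: observed scores, permuted score matrix
# and the restandardization gene-set draws. Permutations shuffle the label
# vector by a sample-index permutation; draws come from a seed stream
# independent of the data, which makes label-swap antisymmetry exact.
gsa_perm_scores <- function(expr, condition, n_perm, seed, var_equal = TRUE) {
  condition <- as.character(condition)
  n <- length(condition)
  i1 <- which(condition == "tumor")
  n1 <- length(i1)
  exhaustive <- FALSE
  n_assign <- suppressWarnings(choose(n, n1))
  if (is.finite(n_assign) && n_assign <= n_perm) {
    assignments <- utils::combn(n, n1, simplify = FALSE)
    perms <- lapply(assignments, function(a) {
      lab <- rep("normal", n)
      lab[a] <- "tumor"
      lab
    })
    exhaustive <- TRUE
    message(sprintf("only %d distinct label assignments; enumerating all",
                    length(perms)))
  } else {
    perms <- with_seed(stream_seed(seed, 1L), {
      lapply(seq_len(n_perm), function(b) condition[sample.int(n)])
    })
  }
  scores0 <- score_engine(expr, i1, which(condition == "normal"), var_equal)
  perm_scores <- vapply(perms, function(lab) {
    as.numeric(score_engine(expr, which(lab == "tumor"),
                            which(lab == "normal"), var_equal))
  }, numeric(nrow(expr)))
  rownames(perm_scores) <- rownames(expr)
  list(observed = scores0, perm_scores = perm_scores,
       n_perm = length(perms), exhaustive = exhaustive)
}

# Random same-size gene-set draws for restandardization (index draws).
gsa_random_sets <- function(n_genes, set_size, n_draws, seed) {
  with_seed(stream_seed(seed, 2L), {
    lapply(seq_len(n_draws), function(j) sample.int(n_genes, set_size))
  })
}

# Restandardized permutation test for one set given a scaffold. The observed
# statistic and every permuted statistic are standardized the same way: by
# the mean/sd of maxmean over k random same-size gene sets drawn on that
# side's own score vector. The symmetry keeps the standardized values
# exchangeable under the null, so the p values are exactly calibrated.
gsa_set_pvalues <- function(scaffold, set_idx, seed, n_draws_per_perm = 10) {
  z0 <- scaffold$observed
  Z <- scaffold$perm_scores
  B <- scaffold$n_perm
  m <- length(set_idx)
  k <- max(2L, as.integer(n_draws_per_perm))
  draws <- gsa_random_sets(length(z0), m, (B + 1L) * k, seed)

  standardize <- function(z, draw_set) {
    cat_v <- vapply(draw_set, function(d) maxmean_fast(z[d]), numeric(1))
    s <- sd(cat_v)
    if (!is.finite(s) || s < 1e-12) s <- 1
    (maxmean_fast(z[set_idx]) - mean(cat_v)) / s
  }
  s_obs_std <- standardize(z0, draws[seq_len(k)])
  s_b_std <- vapply(seq_len(B), function(b) {
    standardize(Z[, b], draws[b * k + seq_len(k)])
  }, numeric(1))

  p_up <- (1 + sum(s_b_std >= s_obs_std)) / (B + 1)
  p_down <- (1 + sum(s_b_std <= s_obs_std)) / (B + 1)
  list(p_up = p_up, p_down = p_down, n_perm = B,
       statistic = maxmean_fast(z0[set_idx]), statistic_std = s_obs_std)
}

#' Restandardized permutation p values for one gene set
#'
#' Tests one gene set in one tissue. The null distribution comes from
#' permuting condition labels; restandardization standardizes the set's
#' maxmean statistic by the mean/sd of maxmean over random same-size gene
#' sets drawn from all scored genes. The observed statistic and every
#' permuted statistic are standardized symmetrically, each by a random-set
#' catalog evaluated on its own score vector, which keeps the standardized
#' values exchangeable and the test exactly calibrated under the null.
#' P values use the add-one estimator, so the smallest attainable value is
#' `1/(n_perm + 1)`.
#' With tiny cohorts (fewer distinct label assignments than `n_perm`) all
#' assignments are enumerated instead.
#'
#' @param expr Numeric matrix (genes x samples) for one tissue.
#' @param condition Per-sample labels (`tumor`/`normal`).
#' @param set Gene ids (row names of `expr`).
#' @param n_perm Number of label permutations (default 100).
#' @param seed Integer seed governing permutations and random-set draws
#'   through independent streams.
#' @param n_draws_per_perm Random gene-set draws per side (observed and each
#'   permutation) used for restandardization; minimum 2.
#' @param var_equal Pooled-variance gene statistic (default) or Welch.
#' @return List with `p_up`, `p_down`, `delta_gsa`, `n_perm`, `statistic`.
#' @export
gsa_pvalues <- function(expr, condition, set, n_perm = 100, seed = 1,
                        n_draws_per_perm = 10, var_equal = TRUE) {
  if (n_perm < 1) abort("n_perm must be >= 1")
  set_idx <- match(as.character(set), rownames(expr))
  if (anyNA(set_idx)) abort("set contains genes absent from `expr`")
  scaffold <- gsa_perm_scores(expr, condition, n_perm, seed, var_equal)
  res <- gsa_set_pvalues(scaffold, set_idx, seed, n_draws_per_perm)
  res$delta_gsa <- delta_gsa(res$p_up, res$p_down)
  res$exhaustive <- scaffold$exhaustive
  res
}

#' Gene Set Analysis across tissues and gene sets
#'
#' Runs the restandardized permutation test for every (paired tissue, set)
#' combination and reports signed delta-GSA scores. Tissues lacking the
#' minimum number of samples per arm are skipped with a message.
#'
#' @param expr logCPM matrix covering all samples (centering is applied
#'   per tissue internally before scoring).
#' @param annotation Sample annotation tibble.
#' @param sets A `gene_set_collection` or named list of gene-id vectors.
#' @param n_perm,seed,n_draws_per_perm,var_equal See [gsa_pvalues()].
#' @param min_per_arm Minimum samples per arm for a tissue to be analysed.
#' @return A tibble of class `chap_gsa`: `tissue`, `set`, `p_up`, `p_down`,
#'   `delta_gsa`, `n_perm`.
#' @export
run_gsa <- function(expr, annotation, sets, n_perm = 100, seed = 1,
                    min_per_arm = 2, n_draws_per_perm = 10, var_equal = TRUE) {
  check_matrix(expr, "expr")
  check_annotation(annotation)
  tissues <- select_paired_tissues(annotation, min_per_arm = min_per_arm)
  skipped <- setdiff(unique(annotation$tissue), tissues)
  if (length(skipped) > 0) {
    message("skipping unpaired tissue(s): ", paste(skipped, collapse = ", "))
  }
  if (length(tissues) == 0) abort("no tissue passes the pairing filter")
  set_idx <- lapply(sets, function(g) {
    idx <- match(as.character(g), rownames(expr))
    idx[!is.na(idx)]
  })
  short <- names(set_idx)[lengths(set_idx) == 0]
  if (length(short) > 0) {
    abort(paste0("gene set(s) with no gene in `expr`: ",
                 paste(short, collapse = ", ")))
  }
  rows <- purrr::map_dfr(seq_along(tissues), function(ti) {
    tissue <- tissues[ti]
    ann <- annotation[annotation$tissue == tissue, ]
    sub <- expr[, ann$sample_id, drop = FALSE]
    sub <- sub - rowMeans(sub)
    tissue_seed <- stream_seed(seed, 10L + ti)
    scaffold <- gsa_perm_scores(sub, ann$condition, n_perm, tissue_seed,
                                var_equal)
    purrr::map_dfr(names(set_idx), function(nm) {
      res <- gsa_set_pvalues(scaffold, set_idx[[nm]], tissue_seed,
                             n_draws_per_perm)
      tibble::tibble(tissue = tissue, set = nm, p_up = res$p_up,
                     p_down = res$p_down,
                     delta_gsa = delta_gsa(res$p_up, res$p_down),
                     n_perm = res$n_perm)
    })
  })
  class(rows) <- c("chap_gsa", class(rows))
  rows
}

#' Per-set group mean delta-GSA
#'
#' The mean signed score of each set across tissues (the bar-graph summary
#' accompanying the heatmaps).
#'
#' @param gsa_result A `chap_gsa` tibble from [run_gsa()].
#' @return Tibble `set`, `mean_delta_gsa`, `n_tissues`.
#' @export
gsa_group_means <- function(gsa_result) {
  dplyr::summarise(dplyr::group_by(gsa_result, .data$set),
                   mean_delta_gsa = mean(.data$delta_gsa),
                   n_tissues = dplyr::n(), .groups = "drop")
}

#' Chaperome versus random non-chaperome background
#'
#' Compares the chaperome maxmean statistic against size-matched gene sets
#' randomly sampled from the non-chaperome genome. For each of
#' `n_samplings` background draws, the permutation distribution of the
#' background set's maxmean serves as the null reference for the observed
#' chaperome statistic; per-tissue signed scores are averaged over the
#' samplings. Background sets never contain chaperome genes.
#'
#' @param expr logCPM matrix over the whole genome (all samples).
#' @param annotation Sample annotation tibble.
#' @param chap_genes Chaperome gene ids.
#' @param n_samplings Number of random background sets (default 100).
#' @param n_perm Label permutations per tissue (default 100).
#' @param seed Integer seed.
#' @param min_per_arm Pairing threshold as in [run_gsa()].
#' @return Tibble `tissue`, `mean_delta_gsa`, `n_samplings`, `n_perm`, with
#'   attribute `background_sets` (list of gene-id vectors drawn).
#' @export
chaperome_vs_background <- function(expr, annotation, chap_genes,
                                    n_samplings = 100, n_perm = 100,
                                    seed = 1, min_per_arm = 2) {
  check_matrix(expr, "expr")
  chap_genes <- as.character(chap_genes)
  chap_idx <- match(chap_genes, rownames(expr))
  chap_idx <- chap_idx[!is.na(chap_idx)]
  non_chap <- setdiff(seq_len(nrow(expr)), chap_idx)
  if (length(non_chap) < 2 * length(chap_idx)) {
    abort("too few non-chaperome genes for background sampling")
  }
  bg_sets <- with_seed(stream_seed(seed, 3L), {
    lapply(seq_len(n_samplings), function(s) {
      sample(non_chap, length(chap_idx))
    })
  })
  tissues <- select_paired_tissues(annotation, min_per_arm = min_per_arm)
  if (length(tissues) == 0) abort("no tissue passes the pairing filter")
  out <- purrr::map_dfr(seq_along(tissues), function(ti) {
    tissue <- tissues[ti]
    ann <- annotation[annotation$tissue == tissue, ]
    sub <- expr[, ann$sample_id, drop = FALSE]
    sub <- sub - rowMeans(sub)
    scaffold <- gsa_perm_scores(sub, ann$condition, n_perm,
                                stream_seed(seed, 10L + ti))
    s_obs <- maxmean_fast(scaffold$observed[chap_idx])
    deltas <- vapply(bg_sets, function(bg) {
      null_stats <- vapply(seq_len(scaffold$n_perm), function(b) {
        maxmean_fast(scaffold$perm_scores[bg, b])
      }, numeric(1))
      p_up <- (1 + sum(null_stats >= s_obs)) / (scaffold$n_perm + 1)
      p_down <- (1 + sum(null_stats <= s_obs)) / (scaffold$n_perm + 1)
      delta_gsa(p_up, p_down)
    }, numeric(1))
    tibble::tibble(tissue = tissue, mean_delta_gsa = mean(deltas),
                   n_samplings = n_samplings, n_perm = scaffold$n_perm)
  })
  attr(out, "background_sets") <-
    lapply(bg_sets, function(i) rownames(expr)[i])
  out
}
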