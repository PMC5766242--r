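#' First principal component of one family in one tissue
#'
#' Computes PC1 of the per-gene-centered samples-by-genes matrix restricted
#' to the family genes present in the expression matrix. The loading vector
#' has unit Euclidean norm; sample scores are the projections onto it. Genes
#' are not scaled to unit variance (PCA on the covariance).
#'
#' @param expr Numeric matrix (genes x samples) for one tissue.
#' @param family_genes Gene ids of the family.
#' @param scale_genes Scale genes to unit variance before PCA (default off).
#' @return List with `loadings` (named, unit norm), `scores` (named by
#'   sample), `genes_used`, `genes_missing`; or `NULL` if fewer than two
#'   family genes are present (the family is skipped for the tissue).
#' @export
fit_tissue_pc1 <- function(expr, family_genes, scale_genes = FALSE) {
  check_matrix(expr, "expr")
  if (ncol(expr) < 3) abort("fit_tissue_pc1 needs at least 3 samples")
  family_genes <- as.character(family_genes)
  present <- intersect(family_genes, rownames(expr))
  missing <- setdiff(family_genes, present)
  if (length(missing) > 0) {
    warn(sprintf("%d family gene(s) absent from matrix: %s",
                 length(missing), paste(head(missing, 5), collapse = ", ")))
  }
  if (length(present) < 2) {
    return(NULL)
  }
  sub <- expr[present, , drop = FALSE]
  sub <- sub - rowMeans(sub)
  pc <- prcomp(t(sub), center = FALSE, scale. = scale_genes)
  w <- pc$rotation[, 1]
  scores <- as.numeric(t(sub) %*% w)
  list(loadings = setNames(as.numeric(w), present),
       scores = setNames(scores, colnames(expr)),
       genes_used = present, genes_missing = missing)
}

#' Tumor/normal separation filter for PC1 scores
#'
#' Student's two-sample t test on the PC1 sample scores; the tissue's
#' loading vector is retained only when tumor and normal scores separate at
#' `p <= threshold` (default 1e-4). Tissues with one arm are never retained.
#'
#' @param scores Named numeric PC1 sample scores.
#' @param condition Per-sample labels (`tumor`/`normal`), aligned to scores.
#' @param threshold Retention p-value threshold.
#' @return List `p_value`, `retained`.
#' @export
separation_filter <- function(scores, condition, threshold = 1e-4) {
  condition <- as.character(condition)
  s1 <- scores[condition == "tumor"]
  s2 <- scores[condition == "normal"]
  if (length(s1) < 2 || length(s2) < 2) {
    return(list(p_value = NA_real_, retained = FALSE))
  }
  p <- tryCatch(t.test(s1, s2, var.equal = TRUE)$p.value,
                error = function(e) NA_real_)
  if (!is.finite(p)) p <- 1
  list(p_value = p, retained = p <= threshold)
}

#' Sign-align per-tissue loading vectors
#'
#' Makes the retained tissue loadings of one family uni-directed so that
#' averaging cannot cancel them. The reference is the tissue with the
#' smallest separation p value; every other vector is flipped when its dot
#' product with the reference (over shared genes) is negative. The global
#' orientation anchors the reference vector so that its entry sum is
#' positive, which makes the M-score move in the same direction as family
#' expression — an upregulated family gains score, a downregulated family
#' loses it. When the entry sum is essentially zero the fallback anchors on
#' the reference tissue's tumor-minus-normal mean score.
#'
#' @param loadings Named list (by tissue) of named loading vectors.
#' @param p_values Named numeric separation p values, same tissues.
#' @param reference_scores Optional PC1 scores of the reference tissue
#'   (named by sample), used only by the degenerate-orientation fallback.
#' @param reference_condition Condition labels aligned to
#'   `reference_scores`.
#' @return List with `loadings` (sign-consistent list) and `reference`
#'   (tissue label).
#' @export
align_and_orient <- function(loadings, p_values, reference_scores = NULL,
                             reference_condition = NULL) {
  if (length(loadings) == 0) abort("no retained tissue loadings to align")
  ref <- names(loadings)[which.min(p_values[names(loadings)])]
  w_ref <- loadings[[ref]]
  aligned <- lapply(names(loadings), function(ti) {
    w <- loadings[[ti]]
    if (ti == ref) return(w)
    shared <- intersect(names(w), names(w_ref))
    d <- sum(w[shared] * w_ref[shared])
    if (d < 0) {
      -w
    } else {
      if (d == 0) warn(sprintf("orthogonal loadings for tissue '%s'; sign kept", ti))
      w
    }
  })
  names(aligned) <- names(loadings)
  flip <- FALSE
  s <- sum(w_ref)
  if (abs(s) > 1e-8) {
    flip <- s < 0
  } else if (!is.null(reference_scores) && !is.null(reference_condition)) {
    shift <- mean(reference_scores[reference_condition == "tumor"]) -
      mean(reference_scores[reference_condition == "normal"])
    flip <- shift < 0
  }
  if (flip) aligned <- lapply(aligned, function(w) -w)
  list(loadings = aligned, reference = ref)
}

#' Average aligned loadings into a universal weight vector
#'
#' Element-wise mean of the sign-consistent tissue loadings (per-gene
#' denominators count only the tissues where the gene was present), followed
#' by renormalization to unit norm so M-score scales stay comparable across
#' families with different numbers of contributing tissues.
#'
#' @param aligned Named list of sign-consistent loading vectors.
#' @return Named numeric weight vector of unit Euclidean norm.
#' @export
combine_meta_pc <- function(aligned) {
  if (length(aligned) == 0) abort("no retained tissues: meta-PC undefined")
  genes <- sort(unique(unlist(lapply(aligned, names))))
  acc <- setNames(numeric(length(genes)), genes)
  cnt <- setNames(numeric(length(genes)), genes)
  for (w in aligned) {
    acc[names(w)] <- acc[names(w)] + w
    cnt[names(w)] <- cnt[names(w)] + 1
  }
  w_bar <- acc / cnt
  nrm <- sqrt(sum(w_bar^2))
  if (nrm == 0) abort("degenerate meta-PC (all-zero mean loading)")
  w_bar / nrm
}

#' Fit the Meta-PCA model
#'
#' For every (family, paired tissue) pair: PC1 loadings of the family genes
#' (Step 1), retention by tumor/normal separation of the PC1 scores at
#' `p_threshold` (Step 2), sign alignment across retained tissues and
#' averaging into the universal weight vector of the family (Step 3).
#' Families with no retained tissue carry no weight vector and are absent
#' from downstream scores.
#'
#' @param expr logCPM matrix over all samples; centered per tissue
#'   internally.
#' @param annotation Sample annotation tibble.
#' @param sets Family `gene_set_collection` (or named list of gene ids).
#' @param p_threshold Step-2 retention threshold (default 1e-4).
#' @param min_per_arm Pairing filter for tissues (default 2).
#' @param scale_genes Passed to [fit_tissue_pc1()].
#' @return An object of class `metapca`: weight vectors, contributing
#'   tissues, and the full per-(family, tissue) loading table.
#' @export
fit_metapca <- function(expr, annotation, sets, p_threshold = 1e-4,
                        min_per_arm = 2, scale_genes = FALSE) {
  check_matrix(expr, "expr")
  check_annotation(annotation)
  tissues <- select_paired_tissues(annotation, min_per_arm = min_per_arm)
  if (length(tissues) == 0) abort("no tissue passes the pairing filter")
  centered <- center_genes(expr, annotation, scope = "per-tissue")

  records <- list()
  for (tissue in tissues) {
    ann <- annotation[annotation$tissue == tissue, ]
    sub <- centered[, ann$sample_id, drop = FALSE]
    for (fam in names(sets)) {
      pc <- suppressWarnings(fit_tissue_pc1(sub, sets[[fam]],
                                            scale_genes = scale_genes))
      if (is.null(pc)) next
      filt <- separation_filter(pc$scores, ann$condition,
                                threshold = p_threshold)
      records[[length(records) + 1]] <- list(
        family = fam, tissue = tissue, p_value = filt$p_value,
        retained = filt$retained, loadings = pc$loadings,
        scores = pc$scores, condition = ann$condition)
    }
  }
  loading_tbl <- tibble::tibble(
    family = vapply(records, `[[`, character(1), "family"),
    tissue = vapply(records, `[[`, character(1), "tissue"),
    p_value = vapply(records, `[[`, numeric(1), "p_value"),
    retained = vapply(records, `[[`, logical(1), "retained"),
    loadings = lapply(records, `[[`, "loadings"))

  weights <- list()
  meta <- list()
  for (fam in names(sets)) {
    rec <- records[vapply(records, function(r) {
      r$family == fam && isTRUE(r$retained)
    }, logical(1))]
    if (length(rec) == 0) next
    lds <- setNames(lapply(rec, `[[`, "loadings"),
                    vapply(rec, `[[`, character(1), "tissue"))
    pv <- setNames(vapply(rec, `[[`, numeric(1), "p_value"), names(lds))
    ref_i <- which.min(pv)
    al <- align_and_orient(lds, pv,
                           reference_scores = rec[[ref_i]]$scores,
                           reference_condition = rec[[ref_i]]$condition)
    weights[[fam]] <- combine_meta_pc(al$loadings)
    meta[[fam]] <- list(tissues = names(lds), reference = al$reference)
  }
  structure(list(weights = weights, families = meta,
                 loading_table = loading_tbl, p_threshold = p_threshold,
                 sets = lapply(sets, as.character),
                 centering_scope = "per-tissue"),
            class = "metapca")
}

#' @export
print.metapca <- function(x, ...) {
  cat("<metapca> ", length(x$weights), " of ", length(x$sets),
      " families with a meta-PC (Step-2 threshold ",
      format(x$p_threshold), ")\n", sep = "")
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a Meta-PCA fit
#'
#' One row per (family, gene) weight of the universal mapping.
#'
#' @param x A `metapca` object.
#' @param ... Unused.
#' @return Tibble `family`, `gene_id`, `weight`.
#' @method tidy metapca
#' @export
tidy.metapca <- function(x, ...) {
  purrr::map_dfr(names(x$weights), function(fam) {
    w <- x$weights[[fam]]
    tibble::tibble(family = fam, gene_id = names(w), weight = as.numeric(w))
  })
}

#' One-line summary of a Meta-PCA fit
#'
#' @param x A `metapca` object.
#' @param ... Unused.
#' @return Tibble with family/tissue bookkeeping columns.
#' @method glance metapca
#' @export
glance.metapca <- function(x, ...) {
  tibble::tibble(
    n_families_fit = length(x$weights),
    n_families_total = length(x$sets),
    n_loadings = nrow(x$loading_table),
    n_retained = sum(x$loading_table$retained),
    p_threshold = x$p_threshold)
}

#' Score samples with fitted Meta-PCs
#'
#' The M-score of a sample for family x is the dot product of the universal
#' weight vector with the sample's centered expression over the family
#' genes; genes missing from the matrix contribute 0. Expression must be
#' centered in the same scope used at fit time (per tissue by default).
#'
#' @param expr Centered logCPM matrix (genes x samples).
#' @param fit A `metapca` object.
#' @param annotation Optional sample annotation to carry through.
#' @return Tibble `sample_id`, `family`, `mscore`, `n_genes_used`,
#'   `low_coverage` (more than half the weight genes missing), plus
#'   annotation columns when given.
#' @export
score_samples <- function(expr, fit, annotation = NULL) {
  check_matrix(expr, "expr")
  out <- purrr::map_dfr(names(fit$weights), function(fam) {
    w <- fit$weights[[fam]]
    present <- intersect(names(w), rownames(expr))
    frac_missing <- 1 - length(present) / length(w)
    if (frac_missing > 0.5) {
      warn(sprintf("family '%s': %.0f%% of weight genes missing from matrix",
                   fam, 100 * frac_missing))
    }
    m <- if (length(present) == 0) {
      rep(0, ncol(expr))
    } else {
      as.numeric(crossprod(expr[present, , drop = FALSE], w[present]))
    }
    tibble::tibble(sample_id = colnames(expr), family = fam, mscore = m,
                   n_genes_used = length(present),
                   low_coverage = frac_missing > 0.5)
  })
  if (!is.null(annotation)) {
    out <- dplyr::left_join(out, annotation, by = "sample_id")
  }
  out
}

#' Polar-plot summary of M-scores
#'
#' Per family and arm: the sample mean and the empirical 5% / 95% quantiles
#' (type-7 interpolation) that draw the mean lines and 90%-range halos of
#' the polar plots.
#'
#' @param mscores Tibble from [score_samples()].
#' @param annotation Sample annotation (needed when `mscores` lacks a
#'   `condition` column).
#' @return Tibble of class `chap_polar`: `family`, `condition`, `mean`,
#'   `q05`, `q95`, `n`.
#' @export
polar_summary <- function(mscores, annotation = NULL) {
  if (!"condition" %in% names(mscores)) {
    if (is.null(annotation)) abort("provide `annotation` with condition labels")
    mscores <- dplyr::left_join(mscores, annotation, by = "sample_id")
  }
  if (!all(c("tumor", "normal") %in% mscores$condition)) {
    abort("both arms must be present for a polar summary")
  }
  out <- dplyr::summarise(
    dplyr::group_by(mscores, .data$family, .data$condition),
    mean = mean(.data$mscore),
    q05 = quantile(.data$mscore, 0.05, type = 7, names = FALSE),
    q95 = quantile(.data$mscore, 0.95, type = 7, names = FALSE),
    n = dplyr::n(), .groups = "drop")
  if (any(out$n < 2)) {
    warn("arm(s) with fewer than 2 samples: quantiles collapse to the value")
  }
  class(out) <- c("chap_polar", class(out))
  out
}

#' Held-out validation of M-scores
#'
#' Stratified 80/20 split of samples (by tissue and condition); a random
#' forest classifier on the per-family M-scores predicts tumor versus
#' normal, reporting held-out overall and per-tissue accuracy.
#'
#' @param mscores Tibble from [score_samples()] including `tissue` and
#'   `condition` columns (score with `annotation`).
#' @param train_frac Training fraction (default 0.8).
#' @param seed Integer seed governing the split and the forest.
#' @param num_trees Trees in the ensemble (default 500).
#' @return List `accuracy`, `per_tissue` (tibble), `n_train`, `n_test`.
#' @export
validate_mscores <- function(mscores, train_frac = 0.8, seed = 1,
                             num_trees = 500) {
  need <- c("sample_id", "family", "mscore", "tissue", "condition")
  missing <- setdiff(need, names(mscores))
  if (length(missing) > 0) {
    abort(paste0("mscores is missing column(s): ",
                 paste(missing, collapse = ", ")))
  }
  wide <- tidyr::pivot_wider(
    dplyr::distinct(mscores, .data$sample_id, .data$family, .data$mscore,
                    .data$tissue, .data$condition),
    names_from = "family", values_from = "mscore", values_fill = 0)
  n_arm <- table(wide$condition)
  if (any(n_arm < 10)) abort("need at least 10 samples per arm to validate")
  strata <- interaction(wide$tissue, wide$condition, drop = TRUE)
  train_idx <- with_seed(stream_seed(seed, 6L), {
    unlist(lapply(split(seq_len(nrow(wide)), strata), function(idx) {
      n_tr <- max(1L, round(train_frac * length(idx)))
      sample(idx, n_tr)
    }), use.names = FALSE)
  })
  test_idx <- setdiff(seq_len(nrow(wide)), train_idx)
  feat_cols <- setdiff(names(wide), c("sample_id", "tissue", "condition"))
  train <- wide[train_idx, ]
  test <- wide[test_idx, ]
  rf <- ranger::ranger(
    x = as.data.frame(train[, feat_cols]),
    y = factor(train$condition, levels = c("normal", "tumor")),
    num.trees = num_trees, seed = stream_seed(seed, 7L))
  pred <- stats::predict(rf, data = as.data.frame(test[, feat_cols]))$predictions
  acc <- mean(as.character(pred) == test$condition)
  per_tissue <- dplyr::summarise(
    dplyr::group_by(tibble::tibble(tissue = test$tissue,
                                   hit = as.character(pred) == test$condition),
                    .data$tissue),
    accuracy = mean(.data$hit), n = dplyr::n(), .groups = "drop")
  list(accuracy = acc, per_tissue = per_tissue,
       n_train = nrow(train), n_test = nrow(test))
}

#' Save or load a Meta-PCA model as JSON
#'
#' The artifact stores, per family, the gene ids, weights, contributing
#' tissues and the orientation reference tissue.
#'
#' @param fit A `metapca` object.
#' @param path File path.
#' @return `write_metapca` returns `path` invisibly; `read_metapca` a
#'   reduced `metapca` object (weights and bookkeeping, no loading table).
#' @export
write_metapca <- function(fit, path) {
  payload <- lapply(names(fit$weights), function(fam) {
    list(genes = names(fit$weights[[fam]]),
         weights = as.numeric(fit$weights[[fam]]),
         tissues = fit$families[[fam]]$tissues,
         orientation_reference = fit$families[[fam]]$reference)
  })
  names(payload) <- names(fit$weights)
  jsonlite::write_json(list(p_threshold = fit$p_threshold,
                            families = payload),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_metapca
#' @export
read_metapca <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  fams <- raw$families
  weights <- lapply(fams, function(f) setNames(as.numeric(f$weights), f$genes))
  meta <- lapply(fams, function(f) {
    list(tissues = f$tissues, reference = f$orientation_reference)
  })
  structure(list(weights = weights, families = meta,
                 loading_table = NULL, p_threshold = raw$p_threshold,
                 sets = lapply(weights, names),
                 centering_scope = "per-tissue"),
            class = "metapca")
}
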