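# one-tissue matrix whose first `n_fam` genes share a programmed tumor shift
shifted_tissue <- function(n_fam = 10, n_bg = 30, n_per_arm = 20, shift = 2,
                           seed = 1) {
  fx <- toy_expr(n_fam + n_bg, 2 * n_per_arm, seed = seed,
                 shift_genes = seq_len(n_fam), shift = shift)
  fx$fam <- rownames(fx$expr)[seq_len(n_fam)]
  fx
}

test_that("PC1 of two perfectly correlated genes is the diagonal", {
  x <- matrix(rnorm(30), 1, 30)
  expr <- rbind(g1 = x[1, ], g2 = x[1, ])
  colnames(expr) <- paste0("s", 1:30)
  pc <- fit_tissue_pc1(expr, c("g1", "g2"))
  expect_equal(abs(unname(pc$loadings)), rep(1 / sqrt(2), 2),
               tolerance = 1e-9)
  expect_equal(sqrt(sum(pc$loadings^2)), 1, tolerance = 1e-9)
})

test_that("PC1 separates arms when the family carries a programmed shift", {
  fx <- shifted_tissue(seed = 7)
  cen <- fx$expr - rowMeans(fx$expr)
  pc <- fit_tissue_pc1(cen, fx$fam)
  filt <- separation_filter(pc$scores, fx$condition)
  expect_lt(filt$p_value, 1e-4)
  expect_true(filt$retained)
  # threshold 1 retains anything
  expect_true(separation_filter(pc$scores, fx$condition,
                                threshold = 1)$retained)
  # missing family genes are masked with a warning
  expect_warning(pc2 <- fit_tissue_pc1(cen, c(fx$fam, "absent")), "absent")
  expect_equal(pc2$genes_missing, "absent")
})

test_that("PCA direction is invariant to positive scaling of expression", {
  fx <- shifted_tissue(seed = 19)
  cen <- fx$expr - rowMeans(fx$expr)
  w1 <- fit_tissue_pc1(cen, fx$fam)$loadings
  w2 <- fit_tissue_pc1(3.7 * cen, fx$fam)$loadings
  expect_equal(abs(sum(w1 * w2)), 1, tolerance = 1e-9)
})

test_that("sign alignment flips antiparallel tissues and preserves the
           disease direction", {
  v <- setNames(c(0.6, 0.8), c("g1", "g2"))
  al <- align_and_orient(list(A = v, B = -v), c(A = 1e-9, B = 1e-6))
  expect_equal(al$reference, "A")
  expect_equal(al$loadings$B, v)

  # downregulated family in a single tissue: tumor M-scores stay below normal
  fx <- shifted_tissue(shift = -2, seed = 23)
  cen <- fx$expr - rowMeans(fx$expr)
  pc <- fit_tissue_pc1(cen, fx$fam)
  al1 <- align_and_orient(list(T1 = pc$loadings), c(T1 = 1e-12),
                          reference_scores = pc$scores,
                          reference_condition = fx$condition)
  w <- combine_meta_pc(al1$loadings)
  m <- as.numeric(crossprod(cen[names(w), ], w))
  shift <- mean(m[fx$condition == "tumor"]) -
    mean(m[fx$condition == "normal"])
  expect_lt(shift, 0)
})

test_that("meta-PC averaging matches hand computations", {
  v <- setNames(c(0.6, 0.8), c("g1", "g2"))
  expect_equal(combine_meta_pc(list(A = v)), v)
  expect_equal(combine_meta_pc(list(A = v, B = v)), v)
  e1 <- setNames(c(1, 0), c("g1", "g2"))
  e2 <- setNames(c(0, 1), c("g1", "g2"))
  expect_equal(combine_meta_pc(list(A = e1, B = e2)),
               setNames(rep(1 / sqrt(2), 2), c("g1", "g2")))
  # invariant to tissue ordering
  withr::with_seed(2, {
    ws <- lapply(1:4, function(i) setNames(rnorm(3), c("a", "b", "c")))
  })
  names(ws) <- paste0("T", 1:4)
  expect_equal(combine_meta_pc(ws), combine_meta_pc(rev(ws)))
  expect_error(combine_meta_pc(list()), "no retained")
})

test_that("M-scores are dot products with masked genes contributing zero", {
  fit <- structure(list(
    weights = list(F1 = setNames(c(0.6, 0.8), c("g1", "g2"))),
    families = list(F1 = list(tissues = "T", reference = "T")),
    sets = list(F1 = c("g1", "g2")), p_threshold = 1e-4),
    class = "metapca")
  expr <- matrix(c(1, 0.5), 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(score_samples(expr, fit)$mscore, 1.0)
  expr0 <- matrix(0, 2, 1, dimnames = list(c("g1", "g2"), "s1"))
  expect_equal(score_samples(expr0, fit)$mscore, 0)
  # more than half the weight genes missing: flagged, rest still scored
  fit3 <- structure(list(
    weights = list(F1 = setNames(c(0.6, 0.48, 0.64),
                                 c("g1", "g2", "g3"))),
    families = list(F1 = list(tissues = "T", reference = "T")),
    sets = list(F1 = c("g1", "g2", "g3")), p_threshold = 1e-4),
    class = "metapca")
  expr1 <- matrix(2, 1, 1, dimnames = list("g1", "s1"))
  expect_warning(sc <- score_samples(expr1, fit3), "missing")
  expect_equal(sc$mscore, 1.2)
  expect_true(sc$low_coverage)
})

test_that("fitted M-score shifts carry the programmed signs", {
  sim <- simulate_cohort(cohort_spec(n_tissues = 3, samples_per_arm = 15,
                                     seed = 31))
  expr <- center_genes(log_cpm(sim$counts), sim$annotation)
  fit <- fit_metapca(expr, sim$annotation, sim$sets)
  sc <- score_samples(expr, fit, sim$annotation)
  shifts <- dplyr::summarise(
    dplyr::group_by(sc, family),
    shift = mean(mscore[condition == "tumor"]) -
      mean(mscore[condition == "normal"]),
    .groups = "drop")
  truth <- dplyr::distinct(sim$truth[, c("family", "delta")])
  joined <- dplyr::inner_join(shifts, truth, by = "family")
  nonzero <- joined[joined$delta != 0, ]
  expect_true(all(sign(nonzero$shift) == sign(nonzero$delta)))
  # null families are mostly filtered at Step 2
  null_fams <- truth$family[truth$delta == 0]
  expect_lt(sum(names(fit$weights) %in% null_fams), 2)
  # when forced through, null families shift less than |delta| = 1 families
  fit_all <- fit_metapca(expr, sim$annotation, sim$sets, p_threshold = 1)
  sc_all <- score_samples(expr, fit_all, sim$annotation)
  sh_all <- dplyr::summarise(
    dplyr::group_by(sc_all, family),
    shift = mean(mscore[condition == "tumor"]) -
      mean(mscore[condition == "normal"]),
    .groups = "drop")
  j2 <- dplyr::inner_join(sh_all, truth, by = "family")
  expect_lt(max(abs(j2$shift[j2$delta == 0])),
            min(abs(j2$shift[abs(j2$delta) == 1])))
})

test_that("tidy/glance expose weights and bookkeeping; JSON round-trips", {
  sim <- simulate_cohort(cohort_spec(n_tissues = 2, samples_per_arm = 10,
                                     n_background = 50, seed = 12))
  expr <- center_genes(log_cpm(sim$counts), sim$annotation)
  fit <- fit_metapca(expr, sim$annotation, sim$sets)
  td <- tidy(fit)
  expect_setequal(unique(td$family), names(fit$weights))
  for (fam in names(fit$weights)) {
    expect_equal(sqrt(sum(td$weight[td$family == fam]^2)), 1,
                 tolerance = 1e-9)
  }
  gl <- glance(fit)
  expect_equal(gl$n_families_total, 10)
  path <- withr::local_tempfile(fileext = ".json")
  write_metapca(fit, path)
  back <- read_metapca(path)
  expect_equal(back$weights, fit$weights, tolerance = 1e-12)
})

test_that("polar summaries match type-7 quantiles and swap with arms", {
  ms <- tibble::tibble(
    sample_id = paste0("s", 1:100), family = "F1",
    mscore = as.numeric(1:100),
    condition = rep(c("tumor", "normal"), each = 50))
  ms$mscore[ms$condition == "normal"] <- 1:50
  ms$mscore[ms$condition == "tumor"] <- 1:50
  pol <- polar_summary(ms)
  expect_equal(pol$mean, rep(25.5, 2))
  # uniform grid 1..100 in one arm: q05 = 5.95, q95 = 95.05 (type 7)
  ms2 <- tibble::tibble(sample_id = paste0("s", 1:102), family = "F",
                        mscore = c(1:100, 0, 0),
                        condition = c(rep("tumor", 100), "normal", "normal"))
  pol2 <- polar_summary(ms2)
  tum <- pol2[pol2$condition == "tumor", ]
  expect_equal(tum$q05, 5.95)
  expect_equal(tum$q95, 95.05)
  # constant scores: halo collapses onto the line
  ms3 <- tibble::tibble(sample_id = paste0("s", 1:6), family = "F",
                        mscore = 2, condition = rep(c("tumor", "normal"), 3))
  pol3 <- polar_summary(ms3)
  expect_equal(pol3$q05, pol3$mean)
  expect_equal(pol3$q95, pol3$mean)
  # swapping arm labels swaps the summaries
  ms4 <- ms2
  ms4$condition <- ifelse(ms2$condition == "tumor", "normal", "tumor")
  pol4 <- polar_summary(ms4)
  expect_equal(pol4[pol4$condition == "normal", c("mean", "q05", "q95")],
               pol2[pol2$condition == "tumor", c("mean", "q05", "q95")])
})

test_that("held-out validation separates signal from permuted labels", {
  sim <- simulate_cohort(cohort_spec(n_tissues = 3, samples_per_arm = 20,
                                     n_background = 80, seed = 44))
  expr <- center_genes(log_cpm(sim$counts), sim$annotation)
  fit <- fit_metapca(expr, sim$annotation, sim$sets)
  sc <- score_samples(expr, fit, sim$annotation)
  v1 <- validate_mscores(sc, seed = 5)
  expect_gt(v1$accuracy, 0.9)
  v1b <- validate_mscores(sc, seed = 5)
  expect_identical(v1$accuracy, v1b$accuracy)
  expect_identical(v1$per_tissue, v1b$per_tissue)

  sc_null <- sc
  perm <- withr::with_seed(9, sample(nrow(sc)))
  sc_null$mscore <- sc$mscore[perm]
  v0 <- validate_mscores(sc_null, seed = 5)
  expect_gt(v0$accuracy, 0.35)
  expect_lt(v0$accuracy, 0.65)
})
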