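test_that("gene scores match the pooled t formula and degenerate rules", {
  expr <- rbind(
    g1 = c(4, 6, 1, 3),    # mean diff 3, pooled sd sqrt(2) -> t = 2.1213
    g2 = c(1, 2, 1, 2),    # identical groups -> 0
    g3 = c(2, 2, 0, 0))    # zero variance both arms -> 0 by rule
  colnames(expr) <- paste0("s", 1:4)
  cond <- c("tumor", "tumor", "normal", "normal")
  expect_warning(sc <- gene_scores(expr, cond), "zero variance")
  expect_equal(unname(sc["g1"]), 3 / sqrt(2), tolerance = 1e-12)
  expect_equal(unname(sc["g2"]), 0)
  expect_equal(unname(sc["g3"]), 0)
  # sign convention: tumor above normal is positive
  expect_gt(sc["g1"], 0)
})

test_that("maxmean matches its definition, tie-break and error cases", {
  s <- c(a = 2, b = -1, c = 3, d = -1)
  expect_equal(maxmean(s, names(s)), 1.25)
  expect_equal(maxmean(c(x = -2, y = -2), c("x", "y")), -2)
  expect_equal(maxmean(c(x = 1, y = -1), c("x", "y")), 0.5) # tie -> positive
  expect_error(maxmean(s, character(0)), "empty")
  expect_error(maxmean(s, "zz"), "without scores")
})

test_that("maxmean equals a brute-force oracle on random vectors", {
  withr::with_seed(11, {
    for (i in 1:1000) {
      n <- sample(2:12, 1)
      s <- setNames(round(rnorm(n), 3), paste0("g", seq_len(n)))
      expect_equal(maxmean(s, names(s)), oracle_maxmean(unname(s)))
    }
  })
})

test_that("permutation p values are reproducible and floor at 1/(B+1)", {
  fx <- toy_expr(120, 16, seed = 5, shift_genes = 1:20, shift = 4)
  set <- rownames(fx$expr)[1:20]
  r1 <- gsa_pvalues(fx$expr, fx$condition, set, n_perm = 99, seed = 42)
  r2 <- gsa_pvalues(fx$expr, fx$condition, set, n_perm = 99, seed = 42)
  expect_identical(r1[c("p_up", "p_down")], r2[c("p_up", "p_down")])
  # a strongly shifted set against a null background: p_up at the add-one
  # floor 1/(n_perm + 1)
  expect_equal(r1$p_up, 1 / 100)
  expect_gte(r1$p_up, 1 / (r1$n_perm + 1))
})

test_that("tiny cohorts fall back to exhaustive label enumeration", {
  fx <- toy_expr(15, 6, seed = 2)
  expect_message(
    res <- gsa_pvalues(fx$expr, fx$condition, rownames(fx$expr)[1:5],
                       n_perm = 100, seed = 1),
    "enumerating")
  expect_true(res$exhaustive)
  expect_equal(res$n_perm, choose(6, 3))
})

test_that("label swap negates delta-GSA exactly for a fixed seed", {
  fx <- toy_expr(80, 20, seed = 9, shift_genes = 1:10, shift = 1.2)
  swapped <- ifelse(fx$condition == "tumor", "normal", "tumor")
  set <- rownames(fx$expr)[1:10]
  a <- gsa_pvalues(fx$expr, fx$condition, set, n_perm = 100, seed = 7)
  b <- gsa_pvalues(fx$expr, swapped, set, n_perm = 100, seed = 7)
  expect_identical(a$p_up, b$p_down)
  expect_identical(a$p_down, b$p_up)
  expect_identical(delta_gsa(a$p_up, a$p_down),
                   -delta_gsa(b$p_up, b$p_down))
})

test_that("delta_gsa arithmetic and bounds", {
  expect_equal(delta_gsa(0, 1), 1)
  expect_equal(delta_gsa(0.5, 0.5), 0)
  expect_equal(delta_gsa(0.2, 0.9), 0.7)
  expect_error(delta_gsa(-0.1, 0.5), "0, 1")
  expect_true(all(abs(delta_gsa(runif(50), runif(50))) <= 1))
})

test_that("run_gsa returns one row per tissue-set pair and recovers effects", {
  spec <- cohort_spec(n_tissues = 2, samples_per_arm = 10,
                      genes_per_family = 8, n_background = 60,
                      delta = matrix(c(2, 0, -2), 3, 2,
                                     dimnames = list(c("UP", "NULL", "DOWN"),
                                                     c("T01", "T02"))),
                      seed = 5)
  sim <- simulate_cohort(spec)
  expr <- center_genes(log_cpm(sim$counts), sim$annotation)
  gsa <- run_gsa(expr, sim$annotation, sim$sets, n_perm = 100, seed = 3)
  expect_equal(nrow(gsa), 6)
  expect_setequal(unique(gsa$tissue), c("T01", "T02"))
  expect_true(all(gsa$delta_gsa[gsa$set == "UP"] > 0.8))
  expect_true(all(gsa$delta_gsa[gsa$set == "DOWN"] < -0.8))
  expect_true(all(abs(gsa$delta_gsa[gsa$set == "NULL"]) < 0.5))
})

test_that("background comparison excludes chaperome genes and is seeded", {
  spec <- cohort_spec(n_tissues = 1, samples_per_arm = 10,
                      genes_per_family = 10, n_background = 300,
                      delta = matrix(1, 4, 1,
                                     dimnames = list(paste0("F", 1:4), "T01")),
                      seed = 8)
  sim <- simulate_cohort(spec)
  expr <- center_genes(log_cpm(sim$counts), sim$annotation)
  chap <- sim$gene_families$entrez_id
  r1 <- chaperome_vs_background(expr, sim$annotation, chap,
                                n_samplings = 20, n_perm = 50, seed = 4)
  r2 <- chaperome_vs_background(expr, sim$annotation, chap,
                                n_samplings = 20, n_perm = 50, seed = 4)
  expect_identical(r1$mean_delta_gsa, r2$mean_delta_gsa)
  bg <- attr(r1, "background_sets")
  expect_identical(bg, attr(r2, "background_sets"))
  for (s in bg) expect_length(intersect(s, as.character(chap)), 0)
  # all chaperome families programmed up: clear positive mean signal
  expect_gt(r1$mean_delta_gsa, 0.5)
  expect_error(
    chaperome_vs_background(expr[1:50, ], sim$annotation,
                            rownames(expr)[1:40]),
    "too few")
})
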